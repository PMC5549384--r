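#' Construct a gene model
#'
#' One transcript's exon/CDS architecture on a chromosome strand, in
#' 1-based fully-closed genomic coordinates. Exons must be sorted
#' ascending and pairwise disjoint and lie within the gene span; the CDS
#' exons are the (sub)intervals carrying coding sequence and their total
#' length must be a positive multiple of 3.
#'
#' @param gene_id,protein_id Identifiers.
#' @param chrom Chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param gene_start,gene_end Gene span, 1-based inclusive.
#' @param exons,cds_exons Data frames with integer columns `start`, `end`.
#' @return An object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, chrom, strand, gene_start, gene_end,
                       exons, cds_exons, protein_id = gene_id) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  cds_exons <- as.data.frame(cds_exons)[, c("start", "end")]
  stopifnot(all(exons$start <= exons$end),
            all(cds_exons$start <= cds_exons$end))
  if (is.unsorted(exons$start, strictly = TRUE) ||
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exons must be sorted ascending and pairwise disjoint",
         call. = FALSE)
  }
  if (min(exons$start) < gene_start || max(exons$end) > gene_end) {
    stop("exons must lie within the gene span", call. = FALSE)
  }
  cds_len <- sum(cds_exons$end - cds_exons$start + 1L)
  if (cds_len <= 0L || cds_len %% 3L != 0L) {
    stop("total CDS length must be a positive multiple of 3", call. = FALSE)
  }
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         gene_start = as.integer(gene_start), gene_end = as.integer(gene_end),
         exons = exons, cds_exons = cds_exons, protein_id = protein_id),
    class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s:%d-%d, %s): %d exon(s), CDS %d nt\n",
              x$gene_id, x$chrom, x$gene_start, x$gene_end, x$strand,
              nrow(x$exons), cds_length(x)))
  invisible(x)
}

#' Total coding length of a gene model in nucleotides
#' @param gm A `GeneModel`.
#' @return Integer CDS length.
#' @export
cds_length <- function(gm) {
  sum(gm$cds_exons$end - gm$cds_exons$start + 1L)
}

#' Per-base CDS-to-genome map
#'
#' Genomic coordinate of every CDS base, in CDS order: position 1 is the
#' first coding base of the transcript, so on the minus strand it maps to
#' the highest genomic coordinate of the CDS.
#'
#' @param gm A `GeneModel`.
#' @return Integer vector of length `cds_length(gm)`.
#' @export
cds_genomic_map <- function(gm) {
  pos <- unlist(Map(seq.int, gm$cds_exons$start, gm$cds_exons$end),
                use.names = FALSE)
  if (gm$strand == "-") rev(pos) else pos
}

#' Protein residue interval to CDS nucleotide interval
#'
#' @param start_aa,end_aa 1-based inclusive residue positions.
#' @return Integer vector `c(cds_start, cds_end)`; the interval length is
#'   three times the residue count.
#' @examples
#' protein_interval_to_cds(41, 65)  # c(121, 195)
#' @export
protein_interval_to_cds <- function(start_aa, end_aa) {
  stopifnot(start_aa >= 1, start_aa <= end_aa)
  c(3L * as.integer(start_aa) - 2L, 3L * as.integer(end_aa))
}

# collapse a sorted integer position vector into closed intervals
.positions_to_blocks <- function(pos) {
  pos <- sort(unique(as.integer(pos)))
  if (length(pos) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  brk <- which(diff(pos) != 1L)
  data.frame(start = pos[c(1L, brk + 1L)], end = pos[c(brk, length(pos))])
}

#' Project a CDS interval to genomic blocks
#'
#' Maps a 1-based inclusive CDS-coordinate interval through the exon
#' structure of a gene model and returns the image as maximal genomic
#' blocks in ascending genomic order. Codons straddling an exon junction
#' split mid-codon; no special casing is needed because the projection is
#' defined per base.
#'
#' @param cds_interval Integer vector `c(start, end)` in CDS coordinates.
#' @param gm A `GeneModel`.
#' @return Data frame with columns `start`, `end` (genomic, 1-based
#'   inclusive, ascending).
#' @export
cds_to_genomic <- function(cds_interval, gm) {
  s <- as.integer(cds_interval[1]); e <- as.integer(cds_interval[2])
  n <- cds_length(gm)
  if (s < 1L || e > n || s > e) {
    stop(sprintf("CDS interval [%d, %d] outside [1, %d]", s, e, n),
         call. = FALSE)
  }
  .positions_to_blocks(cds_genomic_map(gm)[s:e])
}

#' Number of distinct exons intersected by genomic blocks
#'
#' @param blocks Data frame of genomic intervals (`start`, `end`).
#' @param gm A `GeneModel`.
#' @return Integer count of exons with non-empty intersection.
#' @export
exon_span_count <- function(blocks, gm) {
  ex <- gm$exons
  hit <- logical(nrow(ex))
  for (i in seq_len(nrow(blocks))) {
    ov <- blocks$start[i] <= ex$end & blocks$end[i] >= ex$start
    covered <- sum(pmin(ex$end[ov], blocks$end[i]) -
                   pmax(ex$start[ov], blocks$start[i]) + 1L)
    if (covered != blocks$end[i] - blocks$start[i] + 1L) {
      stop("genomic block falls outside the model's exons", call. = FALSE)
    }
    hit <- hit | ov
  }
  sum(hit)
}

#' The four nested context regions of a mapped cluster
#'
#' Region hierarchy used for variant-density comparisons:
#' `cluster_exonic` = the cluster's genomic blocks;
#' `cluster_exonic_plus_intronic` = the contiguous genomic span from the
#' first to the last block (so it includes interleaved introns);
#' `full_mRNA` = the union of all exons; `gene` = the gene span.
#'
#' @param genomic_blocks Data frame of the cluster's genomic blocks.
#' @param gm A `GeneModel`.
#' @return Named list of four descriptors, each a list with `intervals`
#'   (data frame) and `length_nt`.
#' @export
context_regions <- function(genomic_blocks, gm) {
  span <- data.frame(start = min(genomic_blocks$start),
                     end = max(genomic_blocks$end))
  mk <- function(iv) list(intervals = iv,
                          length_nt = sum(iv$end - iv$start + 1L))
  list(
    cluster_exonic = mk(genomic_blocks),
    cluster_exonic_plus_intronic = mk(span),
    full_mRNA = mk(gm$exons),
    gene = mk(data.frame(start = gm$gene_start, end = gm$gene_end))
  )
}

#' Map a protein charge cluster onto the genome
#'
#' Projects a cluster's residue interval to CDS and genomic coordinates
#' and attaches its exon span and the four context regions.
#'
#' @param cluster One-row cluster data frame (as returned by
#'   [find_charge_clusters()]) or a list with `start_aa`, `end_aa`.
#' @param gm A `GeneModel`.
#' @return An object of class `MappedCluster`: list with `cluster`,
#'   `cds_interval`, `genomic_blocks`, `exon_span`, `context_regions`.
#' @export
map_cluster <- function(cluster, gm) {
  cds_iv <- protein_interval_to_cds(cluster$start_aa, cluster$end_aa)
  blocks <- cds_to_genomic(cds_iv, gm)
  structure(
    list(cluster = cluster, gene_id = gm$gene_id, chrom = gm$chrom,
         cds_interval = cds_iv, genomic_blocks = blocks,
         exon_span = exon_span_count(blocks, gm),
         context_regions = context_regions(blocks, gm)),
    class = "MappedCluster")
}

#' @export
print.MappedCluster <- function(x, ...) {
  cat(sprintf("MappedCluster on %s (%s): %d block(s) over %d exon(s)\n",
              x$gene_id, x$chrom, nrow(x$genomic_blocks), x$exon_span))
  invisible(x)
}

#' Extract and translate a cluster's coding sequence from the genome
#'
#' Splices the genomic blocks of a mapped cluster out of the chromosome
#' sequence, orients by strand and translates; used for the
#' translation-consistency check that the projected blocks really encode
#' the cluster's residue segment.
#'
#' @param mapped A `MappedCluster`.
#' @param gm The matching `GeneModel`.
#' @param genome Chromosome sequence: a single string or `DNAString`.
#' @return Amino-acid string of the spliced, oriented blocks.
#' @export
translate_mapped_cluster <- function(mapped, gm, genome) {
  genome <- as.character(genome)
  parts <- substring(genome, mapped$genomic_blocks$start,
                     mapped$genomic_blocks$end)
  nt <- paste(parts, collapse = "")
  dna <- Biostrings::DNAString(nt)
  if (gm$strand == "-") dna <- Biostrings::reverseComplement(dna)
  as.character(Biostrings::translate(dna, no.init.codon = TRUE))
}

#' Spliced CDS of a gene model
#'
#' @param gm A `GeneModel`.
#' @param genome Chromosome sequence (string or `DNAString`).
#' @return CDS nucleotide string in transcript orientation.
#' @export
spliced_cds <- function(gm, genome) {
  genome <- as.character(genome)
  parts <- substring(genome, gm$cds_exons$start, gm$cds_exons$end)
  nt <- paste(parts, collapse = "")
  if (gm$strand == "-") {
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  }
  nt
}
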