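#' Read protein sequences from FASTA
#'
#' @param path Multi-record protein FASTA file.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write protein sequences to FASTA
#' @param proteins Named character vector of sequences.
#' @param path Output file.
#' @export
write_protein_fasta <- function(proteins, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(proteins), path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path Genome FASTA (one record per chromosome).
#' @return Named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a genome to FASTA
#' @param genome Named character vector of chromosome sequences.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon and CDS features with ID/Parent links; the
#' protein identifier travels on the mRNA feature.
#'
#' @param models List of `GeneModel` objects.
#' @param path Output GFF3 file.
#' @export
write_gene_models_gff3 <- function(models, path) {
  feats <- lapply(models, function(gm) {
    tx <- gm$gene_id %+% ".t1"
    n_ex <- nrow(gm$exons); n_cds <- nrow(gm$cds_exons)
    data.frame(
      seqnames = gm$chrom,
      start = c(gm$gene_start, gm$gene_start, gm$exons$start,
                gm$cds_exons$start),
      end = c(gm$gene_end, gm$gene_end, gm$exons$end, gm$cds_exons$end),
      strand = gm$strand,
      type = c("gene", "mRNA", rep("exon", n_ex), rep("CDS", n_cds)),
      ID = c(gm$gene_id, tx, rep(NA, n_ex + n_cds)),
      Parent = c(NA, gm$gene_id, rep(tx, n_ex + n_cds)),
      protein_id = c(NA, gm$protein_id, rep(NA, n_ex + n_cds)),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    df$seqnames, IRanges::IRanges(df$start, df$end), strand = df$strand,
    type = df$type, ID = df$ID, Parent = df$Parent,
    protein_id = df$protein_id)
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects the gene/mRNA/exon/CDS layout written by
#' [write_gene_models_gff3()] (one transcript per gene).
#'
#' @param path GFF3 file.
#' @return Named list of `GeneModel` objects.
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  genes <- df[df$type == "gene", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tx <- df[df$type == "mRNA" & df$Parent == gid, , drop = FALSE]
    txid <- tx$ID[1]
    ex <- df[df$type == "exon" & df$Parent == txid, , drop = FALSE]
    cds <- df[df$type == "CDS" & df$Parent == txid, , drop = FALSE]
    ex <- ex[order(ex$start), ]; cds <- cds[order(cds$start), ]
    pid <- tx$protein_id[1]
    if (is.null(pid) || is.na(pid)) pid <- gid
    out[[gid]] <- gene_model(
      gid, as.character(genes$seqnames[i]), as.character(genes$strand[i]),
      genes$start[i], genes$end[i],
      exons = ex[, c("start", "end")], cds_exons = cds[, c("start", "end")],
      protein_id = pid)
  }
  out
}

#' Write variant records to VCF
#'
#' One alt per record; clinical significance goes to the INFO key
#' `CLNSIG` (spaces encoded as underscores, ClinVar style) and per-source
#' minor allele frequencies to `MAF_1000G`, `MAF_ESP`, `MAF_EXAC`.
#'
#' @param variants Data frame with `chrom`, `pos`, `ref`, `alt` and
#'   optional `clinical_raw`, `maf_1000G`, `maf_ESP`, `maf_EXAC`.
#' @param path Output `.vcf` file.
#' @export
write_variants_vcf <- function(variants, path) {
  n <- nrow(variants)
  gr <- GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(variants$pos, width = nchar(variants$ref)))
  if (n > 0L) {
    names(gr) <- paste0("var", seq_len(n))
  } else {
    # a placeholder contig keeps the header-only file htslib-parseable
    GenomeInfoDb::seqlevels(gr) <- "none"
  }
  fixed <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(variants$ref),
    ALT = Biostrings::DNAStringSetList(as.list(variants$alt)),
    QUAL = rep(NA_real_, n), FILTER = rep(".", n))
  clin <- if ("clinical_raw" %in% names(variants)) {
    gsub(" ", "_", variants$clinical_raw)
  } else rep(NA_character_, n)
  getcol <- function(nm) {
    if (nm %in% names(variants)) variants[[nm]] else rep(NA_real_, n)
  }
  info <- S4Vectors::DataFrame(
    CLNSIG = clin, MAF_1000G = getcol("maf_1000G"),
    MAF_ESP = getcol("maf_ESP"), MAF_EXAC = getcol("maf_EXAC"))
  hdr_info <- S4Vectors::DataFrame(
    Number = rep("1", 4),
    Type = c("String", "Float", "Float", "Float"),
    Description = c("Clinical significance label",
                    "1000 Genomes minor allele frequency",
                    "GO-ESP minor allele frequency",
                    "ExAC minor allele frequency"),
    row.names = c("CLNSIG", "MAF_1000G", "MAF_ESP", "MAF_EXAC"))
  hdr <- VariantAnnotation::VCFHeader(samples = character())
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                      row.names = "fileformat"))
  VariantAnnotation::info(hdr) <- hdr_info
  vcf <- VariantAnnotation::VCF(rowRanges = gr, fixed = fixed,
                                info = info, collapsed = TRUE)
  VariantAnnotation::header(vcf) <- hdr
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Read variant records from VCF
#'
#' Reads a VCF (v4.x), splitting multi-allelic records into one row per
#' alt, and pulls the `CLNSIG` and `MAF_*` INFO keys when present.
#'
#' @param path VCF file.
#' @return Data frame with `chrom`, `pos`, `ref`, `alt`,
#'   `clinical_raw`, `maf_1000G`, `maf_ESP`, `maf_EXAC`.
#' @export
read_variants_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  pick <- function(nm, default) {
    if (nm %in% names(info)) {
      v <- info[[nm]]
      if (is.list(v) || methods::is(v, "List")) {
        v <- vapply(v, function(x) if (length(x)) x[1] else default,
                    default)
      }
      v
    } else rep(default, length(rr))
  }
  clin <- pick("CLNSIG", NA_character_)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    clinical_raw = gsub("_", " ", clin),
    maf_1000G = as.numeric(pick("MAF_1000G", NA_real_)),
    maf_ESP = as.numeric(pick("MAF_ESP", NA_real_)),
    maf_EXAC = as.numeric(pick("MAF_EXAC", NA_real_)),
    stringsAsFactors = FALSE)
}

#' Write a table as TSV
#' @param df Data frame.
#' @param path Output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#' @param path Input file.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Cluster genomic blocks as BED12
#'
#' Converts mapped clusters to 0-based half-open BED12 records, one per
#' cluster, with the genomic blocks as the block structure.
#'
#' @param mapped_list List of `MappedCluster` objects.
#' @param path Output BED file.
#' @export
write_clusters_bed12 <- function(mapped_list, path) {
  rows <- vapply(mapped_list, function(m) {
    b <- m$genomic_blocks
    chrom_start <- min(b$start) - 1L
    sizes <- b$end - b$start + 1L
    starts <- b$start - 1L - chrom_start
    paste(m$chrom, chrom_start, max(b$end),
          m$gene_id %+% "_cc", 0, "+", chrom_start, max(b$end), "0",
          nrow(b), paste(sizes, collapse = ",") %+% ",",
          paste(starts, collapse = ",") %+% ",", sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' @param cohort Output of [simulate_cohort()].
#' @param out_dir Directory (created if missing).
#' @return Named list of the written file paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- list(
    proteins = file.path(out_dir, "proteins.fasta"),
    genome = file.path(out_dir, "genome.fasta"),
    gff3 = file.path(out_dir, "genes.gff3"),
    vcf = file.path(out_dir, "variants.vcf"),
    changes = file.path(out_dir, "protein_changes.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_protein_fasta(
    vapply(cohort$proteins, `[[`, character(1), "seq"), f$proteins)
  genome <- vapply(cohort$genes, `[[`, character(1), "genome")
  names(genome) <- vapply(cohort$genes,
                          function(g) g$model$chrom, character(1))
  write_genome_fasta(genome, f$genome)
  write_gene_models_gff3(lapply(cohort$genes, `[[`, "model"), f$gff3)
  vs <- do.call(rbind, lapply(cohort$variants, `[[`, "variants"))
  rownames(vs) <- NULL
  write_variants_vcf(vs, f$vcf)
  write_tsv(data.frame(cluster_id = seq_along(cohort$changes$changes),
                       protein_change = cohort$changes$changes),
            f$changes)
  truth <- list(clusters = cohort$truth,
                variants = do.call(rbind, lapply(cohort$variants,
                                                 `[[`, "truth")),
                changes = cohort$changes$truth)
  jsonlite::write_json(truth, f$truth, dataframe = "columns",
                       na = "null", auto_unbox = FALSE, digits = NA)
  f
}
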