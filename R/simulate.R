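#' Default simulation configuration
#'
#' All mixtures the generator plants, with defaults set to the study
#' conditions the pipeline is validated against: cluster length
#' statistics of 24.2 +/- 3.9 aa for negative and 27.8 +/- 7.6 aa for
#' positive clusters (truncated to the 20-75 aa definition), an
#' exon-span mixture of 67% / 31% / 2% for clusters encoded by one, two
#' and three or more exons, a nucleotide variant-type mixture of 80%
#' SNV / 12% deletion / 8% insertion, a lowest-ExAC-MAF-bin share of
#' 78% (negative) or 85% (positive), a protein-change category mixture
#' of 55% substitution / 28% synonymous / 12.75% deletion / 4.25%
#' insertion, Glu/Asp affected-residue weights of 34.5% / 22%, and a
#' 54% share of single-residue insertions.
#'
#' @param sign Cluster sign the cohort emulates (`"negative"` or
#'   `"positive"`); switches the length, MAF and clinical defaults.
#' @return A list of class `SimulationConfig`.
#' @export
default_sim_config <- function(sign = c("negative", "positive")) {
  sign <- match.arg(sign)
  res20 <- names(Biostrings::AMINO_ACID_CODE)[1:20]
  uncharged <- setdiff(res20, c("D", "E", "K", "R"))
  w <- stats::setNames(numeric(20), res20)
  if (sign == "negative") {
    w["E"] <- 0.345; w["D"] <- 0.22
    w[uncharged] <- (1 - 0.345 - 0.22) / length(uncharged)
  } else {
    w["R"] <- 0.33; w["K"] <- 0.24
    w[uncharged] <- (1 - 0.33 - 0.24) / length(uncharged)
  }
  # insertion length spectrum: 54% single residue, geometric decay to 12
  tail_w <- 0.6^(0:10)
  ins_len <- c(0.54, 0.46 * tail_w / sum(tail_w))
  names(ins_len) <- as.character(1:12)

  dest_default <- stats::setNames(rep(0.25, 4), AA_GROUPS)
  dest_acidic <- c(hydrophobic = 0.202, polar = 0.421,
                   acidic = 0.1885, basic = 0.1885)
  dest_basic <- c(hydrophobic = 0.25, polar = 0.35,
                  acidic = 0.15, basic = 0.25)

  cfg <- list(
    sign = sign,
    n_genes = 100L,
    protein_length = c(min = 200L, max = 500L),
    background_charge_freq = 0.02,
    cluster_rate = 1,
    cluster_length = if (sign == "negative") c(mean = 24.2, sd = 3.9)
                     else c(mean = 27.8, sd = 7.6),
    cluster_length_bounds = c(20L, 75L),
    cluster_charge_density = 0.55,
    exon_span_mix = c(`1` = 0.67, `2` = 0.31, `3` = 0.02),
    extra_intron_prob = 0.4,
    intron_length = c(min = 60L, max = 400L),
    utr_length = c(min = 50L, max = 150L),
    flank_length = 200L,
    variant_density = c(cluster_exonic = 0.25, mrna_other = 0.12,
                        gene_other = 0.08),
    variant_type_mix = c(SNV = 0.80, deletion = 0.12, insertion = 0.08),
    indel_max_len = 3L,
    maf_bin_mix = if (sign == "negative")
      c(lt_0.005 = 0.78, `0.005_to_0.01` = 0.10,
        `0.01_to_0.05` = 0.07, ge_0.05 = 0.05)
    else
      c(lt_0.005 = 0.85, `0.005_to_0.01` = 0.07,
        `0.01_to_0.05` = 0.05, ge_0.05 = 0.03),
    maf_unspecified_rate = 0.15,
    clinical_mix = if (sign == "negative")
      c(Pathogenic = 0.08, `Likely pathogenic` = 0.06,
        `risk factor` = 0.02, Benign = 0.25, `Likely benign` = 0.21,
        `Uncertain significance` = 0.23, unspecified = 0.15)
    else
      c(Pathogenic = 0.18, `Likely pathogenic` = 0.12,
        `risk factor` = 0.04, Benign = 0.12, `Likely benign` = 0.10,
        `Uncertain significance` = 0.29, unspecified = 0.15),
    change_category_mix = c(substitution = 0.55, synonymous = 0.28,
                            deletion = 0.1275, insertion = 0.0425),
    affected_residue_weights = w,
    substitution_dest_mix = list(
      hydrophobic = dest_default, polar = dest_default,
      acidic = dest_acidic, basic = dest_basic),
    insertion_length_spectrum = ins_len,
    insertion_group_mix = c(hydrophobic = 0.03, polar = 0.06,
                            acidic = 0.88, basic = 0.03),
    alpha = 0.01,
    p0_floor = 0.05
  )
  structure(validate_sim_config(cfg), class = "SimulationConfig")
}

#' Validate a simulation configuration
#'
#' Checks that every mixture sums to one (tolerance 1e-9) and that the
#' planted cluster length bounds stay within the 20-75 aa definition.
#'
#' @param cfg Configuration list.
#' @return `cfg`, invisibly modified only by integer coercions.
#' @export
validate_sim_config <- function(cfg) {
  mixes <- list(exon_span_mix = cfg$exon_span_mix,
                variant_type_mix = cfg$variant_type_mix,
                maf_bin_mix = cfg$maf_bin_mix,
                clinical_mix = cfg$clinical_mix,
                change_category_mix = cfg$change_category_mix,
                affected_residue_weights = cfg$affected_residue_weights,
                insertion_length_spectrum = cfg$insertion_length_spectrum,
                insertion_group_mix = cfg$insertion_group_mix)
  for (nm in names(mixes)) {
    if (abs(sum(mixes[[nm]]) - 1) > 1e-9) {
      stop(sprintf("mixture `%s` must sum to 1 (got %.12f)", nm,
                   sum(mixes[[nm]])), call. = FALSE)
    }
  }
  b <- cfg$cluster_length_bounds
  if (b[1] < 20L || b[2] > 75L || b[1] > b[2]) {
    stop("cluster length bounds must lie within [20, 75]", call. = FALSE)
  }
  if (any(cfg$variant_density < 0) || any(cfg$variant_density > 1)) {
    stop("variant densities must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

# truncated-normal draw by rejection
.rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

.UNCHARGED <- setdiff(names(Biostrings::AMINO_ACID_CODE)[1:20],
                      c("D", "E", "K", "R"))

#' Simulate a protein with a planted charge cluster
#'
#' Background residues are drawn i.i.d. from a low-charge composition
#' (each of D, E, K, R at `background_charge_freq`, the remainder spread
#' uniformly over the 16 uncharged residues). With probability
#' `cluster_rate` one cluster segment is planted: its length is drawn
#' from the sign's truncated normal, a `cluster_charge_density` share of
#' its residues carry the cluster's sign (first and last always do), the
#' rest are uncharged, and it contains no opposite-sign residue. One
#' opposite-sign residue is written immediately on each side of the
#' plant so detected boundaries stay tight.
#'
#' @param cfg A `SimulationConfig`.
#' @param seed Optional integer seed.
#' @param protein_id Identifier for the truth record.
#' @return List with `seq` (string) and `truth` (zero- or one-row data
#'   frame with `protein_id`, `sign`, `start_aa`, `end_aa`, `length_aa`).
#' @export
simulate_protein <- function(cfg, seed = NULL, protein_id = "prot1") {
  if (!is.null(seed)) set.seed(seed)
  n <- sample(cfg$protein_length["min"]:cfg$protein_length["max"], 1L)
  res20 <- names(Biostrings::AMINO_ACID_CODE)[1:20]
  p_bg <- stats::setNames(rep(0, 20), res20)
  p_bg[c("D", "E", "K", "R")] <- cfg$background_charge_freq
  p_bg[.UNCHARGED] <- (1 - 4 * cfg$background_charge_freq) / 16
  seq <- sample(res20, n, replace = TRUE, prob = p_bg)

  truth <- data.frame(protein_id = character(), sign = character(),
                      start_aa = integer(), end_aa = integer(),
                      length_aa = integer())
  if (stats::runif(1) < cfg$cluster_rate) {
    len <- round(.rtrunc_norm(1, cfg$cluster_length["mean"],
                              cfg$cluster_length["sd"],
                              cfg$cluster_length_bounds[1],
                              cfg$cluster_length_bounds[2]))
    if (len + 22L > n) {
      stop("infeasible config: planted cluster longer than the protein",
           call. = FALSE)
    }
    same_pool <- if (cfg$sign == "negative") c("D", "E") else c("K", "R")
    opp_pool <- if (cfg$sign == "negative") c("K", "R") else c("D", "E")
    k <- max(2L, round(cfg$cluster_charge_density * len))
    seg <- sample(.UNCHARGED, len, replace = TRUE)
    charged_at <- c(1L, len)
    if (k > 2L && len > 2L) {
      charged_at <- c(charged_at, sample(2:(len - 1L), k - 2L))
    }
    seg[charged_at] <- sample(same_pool, length(charged_at), replace = TRUE)
    start <- sample(11:(n - len - 10L), 1L)
    seq[start:(start + len - 1L)] <- seg
    seq[start - 1L] <- sample(opp_pool, 1L)
    seq[start + len] <- sample(opp_pool, 1L)
    truth <- data.frame(protein_id = protein_id, sign = cfg$sign,
                        start_aa = start, end_aa = start + len - 1L,
                        length_aa = len)
  }
  list(seq = paste(seq, collapse = ""), truth = truth)
}

# synonymous codon sets, built once from the standard genetic code
.CODON_SETS <- split(names(Biostrings::GENETIC_CODE),
                     unname(Biostrings::GENETIC_CODE))

# back-translate a protein (plus one stop codon) with uniform synonymous
# codon choice
.back_translate <- function(seq) {
  aa <- c(strsplit(seq, "")[[1]], "*")
  codons <- vapply(aa, function(a) {
    set <- .CODON_SETS[[a]]
    set[sample.int(length(set), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a gene model encoding a protein
#'
#' Back-translates the protein to a CDS with uniform synonymous codon
#' choice (one stop codon appended), inserts introns so that the planted
#' cluster's coding sequence spans one, two or three exons according to
#' the configured exon-span mixture (cut points fall strictly inside the
#' cluster's CDS interval and may split codons), optionally adds one
#' intron outside the cluster, pads the transcript with UTR exon
#' sequence and intergenic flanks, and draws a strand at random. The
#' spliced CDS re-translates to the protein exactly by construction.
#'
#' @param protein Output of [simulate_protein()] (needs one planted
#'   cluster).
#' @param cfg A `SimulationConfig`.
#' @param seed Optional integer seed.
#' @param gene_id,chrom Identifiers for the model.
#' @return List with `model` (a `GeneModel`), `genome` (plus-strand
#'   chromosome string) and `truth` (one-row data frame with the drawn
#'   `exon_span`).
#' @export
simulate_gene_model <- function(protein, cfg, seed = NULL,
                                gene_id = "gene1", chrom = "chr1") {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(protein$truth) == 0L) {
    stop("protein carries no planted cluster", call. = FALSE)
  }
  tr <- protein$truth[1, ]
  cds <- .back_translate(protein$seq)
  cds_len <- nchar(cds)
  cc_cds <- protein_interval_to_cds(tr$start_aa, tr$end_aa)

  span <- as.integer(sample(names(cfg$exon_span_mix), 1L,
                            prob = cfg$exon_span_mix))
  cuts <- integer(0)
  if (span > 1L) {
    cuts <- sort(sample(cc_cds[1]:(cc_cds[2] - 1L), span - 1L))
  }
  if (stats::runif(1) < cfg$extra_intron_prob) {
    outside <- setdiff(1:(cds_len - 1L), cc_cds[1]:(cc_cds[2] - 1L))
    if (length(outside) > 0L) {
      cuts <- sort(c(cuts, sample(outside, 1L)))
    }
  }

  # transcript-orientation layout: 5'UTR, CDS pieces with introns, 3'UTR
  utr5 <- sample(cfg$utr_length["min"]:cfg$utr_length["max"], 1L)
  utr3 <- sample(cfg$utr_length["min"]:cfg$utr_length["max"], 1L)
  piece_bounds <- cbind(start = c(1L, cuts + 1L), end = c(cuts, cds_len))
  n_piece <- nrow(piece_bounds)
  intron_len <- sample(cfg$intron_length["min"]:cfg$intron_length["max"],
                       max(n_piece - 1L, 0L), replace = TRUE)

  locus <- .rand_dna(utr5)
  exon_tx <- data.frame(start = integer(), end = integer())
  cds_tx <- data.frame(start = integer(), end = integer())
  cursor <- utr5
  exon_open <- 1L  # first exon starts with the 5'UTR
  for (i in seq_len(n_piece)) {
    piece <- substr(cds, piece_bounds[i, "start"], piece_bounds[i, "end"])
    locus <- locus %+% piece
    cds_tx <- rbind(cds_tx, data.frame(start = cursor + 1L,
                                       end = cursor + nchar(piece)))
    cursor <- cursor + nchar(piece)
    if (i < n_piece) {
      exon_tx <- rbind(exon_tx, data.frame(start = exon_open, end = cursor))
      locus <- locus %+% .rand_dna(intron_len[i])
      cursor <- cursor + intron_len[i]
      exon_open <- cursor + 1L
    }
  }
  locus <- locus %+% .rand_dna(utr3)
  cursor <- cursor + utr3
  exon_tx <- rbind(exon_tx, data.frame(start = exon_open, end = cursor))

  gene_len <- cursor
  flank <- cfg$flank_length
  strand <- sample(c("+", "-"), 1L)
  if (strand == "-") {
    locus <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(locus)))
    flip <- function(iv) {
      data.frame(start = gene_len - iv$end + 1L,
                 end = gene_len - iv$start + 1L)[rev(seq_len(nrow(iv))), ,
                                                 drop = FALSE]
    }
    exon_tx <- flip(exon_tx)
    cds_tx <- flip(cds_tx)
  }
  genome <- .rand_dna(flank) %+% locus %+% .rand_dna(flank)
  shift <- function(iv) data.frame(start = iv$start + flank,
                                   end = iv$end + flank)
  gm <- gene_model(gene_id, chrom, strand,
                   gene_start = flank + 1L, gene_end = flank + gene_len,
                   exons = shift(exon_tx), cds_exons = shift(cds_tx),
                   protein_id = tr$protein_id)
  truth <- cbind(tr, data.frame(gene_id = gene_id, chrom = chrom,
                                strand = strand, exon_span = span))
  list(model = gm, genome = genome, truth = truth)
}

.draw_maf <- function(n, cfg) {
  edges <- list(lt_0.005 = c(0, 0.005), `0.005_to_0.01` = c(0.005, 0.01),
                `0.01_to_0.05` = c(0.01, 0.05), ge_0.05 = c(0.05, 0.5))
  bin <- sample(names(cfg$maf_bin_mix), n, replace = TRUE,
                prob = cfg$maf_bin_mix)
  val <- vapply(bin, function(b) {
    stats::runif(1, edges[[b]][1], edges[[b]][2])
  }, numeric(1))
  unspec <- stats::runif(n) < cfg$maf_unspecified_rate
  val[unspec] <- NA_real_
  bin[unspec] <- "unspecified"
  list(value = unname(val), bin = unname(bin))
}

#' Simulate variant records over a gene
#'
#' Each genomic position of the gene carries an independent Bernoulli
#' chance of hosting a variant, with the density set per region class
#' (cluster exonic blocks, other exonic sequence, remaining gene
#' sequence). The variant type is drawn from the configured mixture and
#' realized as concrete, anchored ref/alt alleles against the genomic
#' sequence; per-source minor allele frequencies are drawn by first
#' picking a bin from the configured bin mixture (a configured share is
#' left unspecified) and then uniformly within the bin; the clinical
#' label is drawn from the configured label mixture. Overlapping records
#' are suppressed so every ref allele matches the genome.
#'
#' @param sim_gene Output of [simulate_gene_model()].
#' @param cfg A `SimulationConfig`.
#' @param seed Optional integer seed.
#' @return List with `variants` (data frame ready for
#'   [annotate_variants()]) and `truth` (per-variant planted type, MAF
#'   bins and clinical class).
#' @export
simulate_variants <- function(sim_gene, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gm <- sim_gene$model
  genome <- sim_gene$genome
  tr <- sim_gene$truth[1, ]
  mapped_blocks <- cds_to_genomic(
    protein_interval_to_cds(tr$start_aa, tr$end_aa), gm)

  pos_all <- gm$gene_start:gm$gene_end
  in_cc <- rep(FALSE, length(pos_all))
  for (i in seq_len(nrow(mapped_blocks))) {
    in_cc <- in_cc | (pos_all >= mapped_blocks$start[i] &
                      pos_all <= mapped_blocks$end[i])
  }
  in_exon <- rep(FALSE, length(pos_all))
  for (i in seq_len(nrow(gm$exons))) {
    in_exon <- in_exon | (pos_all >= gm$exons$start[i] &
                          pos_all <= gm$exons$end[i])
  }
  dens <- ifelse(in_cc, cfg$variant_density["cluster_exonic"],
                 ifelse(in_exon, cfg$variant_density["mrna_other"],
                        cfg$variant_density["gene_other"]))
  if (any(dens > 1)) stop("variant density above 1", call. = FALSE)
  hit <- pos_all[stats::runif(length(pos_all)) < dens]

  bases <- c("A", "C", "G", "T")
  rows <- list()
  last_end <- -1L
  for (p in hit) {
    if (p <= last_end) next  # no overlapping records
    type <- sample(names(cfg$variant_type_mix), 1L,
                   prob = cfg$variant_type_mix)
    ref_base <- substr(genome, p, p)
    if (type == "SNV") {
      ref <- ref_base
      alt <- sample(setdiff(bases, ref_base), 1L)
      span_end <- p
    } else if (type == "insertion") {
      ins_len <- sample.int(cfg$indel_max_len, 1L)
      ref <- ref_base
      alt <- ref_base %+% .rand_dna(ins_len)
      span_end <- p
    } else {
      del_len <- sample.int(cfg$indel_max_len, 1L)
      if (p + del_len > gm$gene_end) next
      ref <- substr(genome, p, p + del_len)
      alt <- ref_base
      span_end <- p + del_len
    }
    rows[[length(rows) + 1L]] <-
      data.frame(pos = p, ref = ref, alt = alt, true_type = type)
    last_end <- span_end
  }
  if (length(rows) == 0L) {
    v <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), clinical_raw = character(),
                    maf_1000G = numeric(), maf_ESP = numeric(),
                    maf_EXAC = numeric())
    return(list(variants = v, truth = v))
  }
  v <- do.call(rbind, rows)
  n <- nrow(v)
  clin <- sample(names(cfg$clinical_mix), n, replace = TRUE,
                 prob = cfg$clinical_mix)
  clin_raw <- ifelse(clin == "unspecified", NA_character_, clin)
  m1 <- .draw_maf(n, cfg); m2 <- .draw_maf(n, cfg); m3 <- .draw_maf(n, cfg)
  variants <- data.frame(
    chrom = gm$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    clinical_raw = clin_raw, maf_1000G = m1$value, maf_ESP = m2$value,
    maf_EXAC = m3$value, stringsAsFactors = FALSE)
  truth <- data.frame(
    chrom = gm$chrom, pos = v$pos, true_type = v$true_type,
    true_clinical = clinical_class(clin_raw),
    true_bin_1000G = m1$bin, true_bin_ESP = m2$bin, true_bin_EXAC = m3$bin,
    stringsAsFactors = FALSE)
  list(variants = variants, truth = truth)
}

.sample_group_residue <- function(group) {
  pools <- list(hydrophobic = strsplit("AVLIMFWP", "")[[1]],
                polar = strsplit("GSTCYNQH", "")[[1]],
                acidic = c("E", "D"), basic = c("K", "R"))
  pool <- pools[[group]]
  pool[sample.int(length(pool), 1L)]
}

#' Simulate HGVS.p-style protein-change strings
#'
#' Draws a change category (substitution, synonymous, insertion,
#' deletion) from the configured mixture for each record. The affected
#' residue follows the configured per-residue weights; substitution
#' destinations are drawn group-first from the configured
#' destination-group distribution of the source's group, then uniformly
#' within the destination group (never reproducing the source residue);
#' insertion lengths follow the configured spectrum and inserted
#' residues the configured group mix. Every emitted string round-trips
#' through [parse_protein_change()] to its truth record.
#'
#' @param cfg A `SimulationConfig`.
#' @param n Number of records.
#' @param seed Optional integer seed.
#' @return List with `changes` (character vector) and `truth` (data
#'   frame with `kind`, `position`, `ref_res`, `alt_res`,
#'   `inserted_len`, `inserted_seq`).
#' @export
simulate_protein_changes <- function(cfg, n = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kinds <- sample(names(cfg$change_category_mix), n, replace = TRUE,
                  prob = cfg$change_category_mix)
  w <- cfg$affected_residue_weights
  aa3 <- Biostrings::AMINO_ACID_CODE
  out <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- sample.int(60L, 1L)
    kind <- kinds[i]
    ref <- sample(names(w), 1L, prob = w)
    alt <- NA_character_; ins <- NA_character_
    if (kind == "substitution") {
      dest_mix <- cfg$substitution_dest_mix[[aa_group(ref)]]
      repeat {
        g <- sample(names(dest_mix), 1L, prob = dest_mix)
        alt <- .sample_group_residue(g)
        if (alt != ref) break
      }
      out[i] <- aa3[ref] %+% pos %+% aa3[alt]
    } else if (kind == "synonymous") {
      alt <- ref
      out[i] <- aa3[ref] %+% pos %+% aa3[ref]
    } else if (kind == "deletion") {
      out[i] <- aa3[ref] %+% pos %+% "del"
    } else {
      len <- as.integer(sample(names(cfg$insertion_length_spectrum), 1L,
                               prob = cfg$insertion_length_spectrum))
      grp <- sample(names(cfg$insertion_group_mix), len, replace = TRUE,
                    prob = cfg$insertion_group_mix)
      ins <- paste(vapply(grp, .sample_group_residue, character(1)),
                   collapse = "")
      flank2 <- sample(names(w), 1L, prob = w)
      run3 <- paste(aa3[strsplit(ins, "")[[1]]], collapse = "")
      out[i] <- aa3[ref] %+% pos %+% "_" %+% aa3[flank2] %+%
        (pos + 1L) %+% "ins" %+% run3
    }
    truth[[i]] <- data.frame(kind = kind, position = pos, ref_res = ref,
                             alt_res = alt,
                             inserted_len = if (is.na(ins)) 0L
                                            else nchar(ins),
                             inserted_seq = ins, stringsAsFactors = FALSE)
  }
  list(changes = out, truth = do.call(rbind, truth))
}

#' Simulate a full cohort and write its files
#'
#' Generates `cfg$n_genes` proteins, gene models, chromosomes and
#' variant sets plus one protein-change set, writing protein FASTA,
#' genome FASTA, GFF3, VCF, protein-change TSV and a truth JSON to
#' `out_dir`. Each gene lives on its own chromosome. Identical
#' (configuration, seed) pairs produce byte-identical files.
#'
#' @param cfg A `SimulationConfig`.
#' @param seed Integer seed for the whole cohort.
#' @param out_dir Output directory (created if missing); `NULL` returns
#'   the in-memory cohort only.
#' @param n_changes Number of protein-change records.
#' @return Invisibly, a list with `proteins`, `genes` (list of
#'   [simulate_gene_model()] outputs), `variants`, `changes`, `truth`
#'   and (when written) `files`.
#' @export
simulate_cohort <- function(cfg, seed = 1L, out_dir = NULL,
                            n_changes = 1000L) {
  set.seed(seed)
  proteins <- list(); genes <- list(); variants <- list(); truths <- list()
  for (i in seq_len(cfg$n_genes)) {
    pid <- sprintf("prot%04d", i)
    gid <- sprintf("gene%04d", i)
    chrom <- sprintf("chr_%s", gid)
    pr <- simulate_protein(cfg, protein_id = pid)
    g <- simulate_gene_model(pr, cfg, gene_id = gid, chrom = chrom)
    vs <- simulate_variants(g, cfg)
    proteins[[pid]] <- pr
    genes[[gid]] <- g
    variants[[gid]] <- vs
    truths[[gid]] <- g$truth
  }
  changes <- simulate_protein_changes(cfg, n = n_changes)
  cohort <- list(proteins = proteins, genes = genes, variants = variants,
                 changes = changes, truth = do.call(rbind, truths))
  if (!is.null(out_dir)) {
    cohort$files <- write_cohort(cohort, out_dir)
  }
  invisible(cohort)
}
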