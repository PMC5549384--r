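#' Run the full charge-cluster variation pipeline
#'
#' Executes detect -> map -> annotate -> aachange -> report over one set
#' of input files: detects charge clusters in the proteins, projects
#' each onto its gene model, overlaps the variant set with the four
#' nested context regions, computes the variant-fraction table and the
#' classification tallies, tallies amino-acid exchanges from the
#' protein-change set, and runs the density ANOVA (with Tukey HSD) and
#' the type-by-group chi-square. All thresholds live in `config` and are
#' echoed into the run manifest together with input digests.
#'
#' @param config List with input paths `proteins_fasta`, `genome_fasta`,
#'   `gff3`, `vcf`, optionally `changes_tsv`, and parameters `alpha`
#'   (default 0.01), `p0_floor` (default 0.05).
#' @param out_dir Optional directory for the report files.
#' @param seed Integer seed recorded in the manifest (the analysis
#'   itself is deterministic).
#' @return A report bundle: list with `clusters`, `mapped`,
#'   `annotations`, `fraction_table`, `tallies`, `exchange`,
#'   `aa_tables`, `tests`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = 0L) {
  alpha <- config$alpha %||% 0.01
  p0_floor <- config$p0_floor %||% 0.05
  n_warn <- 0L
  wh <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      n_warn <<- n_warn + 1L
      invokeRestart("muffleWarning")
    })
  }

  proteins <- read_protein_fasta(config$proteins_fasta)
  clusters <- wh(detect_charge_clusters(proteins, alpha, p0_floor))

  models <- read_gene_models_gff3(config$gff3)
  genome <- read_genome_fasta(config$genome_fasta)
  by_protein <- stats::setNames(
    models, vapply(models, `[[`, character(1), "protein_id"))

  variants <- read_variants_vcf(config$vcf)

  mapped <- list(); annotations <- list(); frac_rows <- list()
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    gm <- by_protein[[cl$protein_id]]
    if (is.null(gm)) next
    cl_id <- sprintf("%s_%s_%d", gm$gene_id, cl$sign, cl$start_aa)
    m <- map_cluster(cl, gm)
    mapped[[cl_id]] <- m
    ann <- wh(annotate_variants(variants, m, gm, genome[[gm$chrom]]))
    if (nrow(ann) > 0L) ann <- cbind(cluster_id = cl_id, ann)
    annotations[[cl_id]] <- ann
    for (tag in names(m$context_regions)) {
      reg <- m$context_regions[[tag]]
      frac_rows[[length(frac_rows) + 1L]] <- data.frame(
        cluster_id = cl_id, region_tag = tag,
        variant_count = sum(ann$region_tag == tag),
        region_length_nt = reg$length_nt)
    }
  }
  fraction_table <- variant_fraction_table(
    do.call(rbind, frac_rows) %||%
      data.frame(cluster_id = character(), region_tag = character(),
                 variant_count = integer(), region_length_nt = integer()))
  ann_all <- do.call(rbind, annotations)
  if (is.null(ann_all)) {
    ann_all <- data.frame(cluster_id = character(), region_tag = character(),
                          var_type = character(), consequence = character(),
                          clinical_class = character(),
                          maf_bin_EXAC = character())
  }
  rownames(ann_all) <- NULL

  cc_ann <- ann_all[ann_all$region_tag == "cluster_exonic", , drop = FALSE]
  tallies <- list(
    var_type = table(cc_ann$var_type),
    consequence = table(cc_ann$consequence),
    clinical_class = table(
      cc_ann$clinical_class[cc_ann$clinical_class != "unspecified"]),
    maf_bin_EXAC = table(
      cc_ann$maf_bin_EXAC[cc_ann$maf_bin_EXAC != "unspecified"]))

  exchange <- NULL; aa_tables <- NULL
  if (!is.null(config$changes_tsv)) {
    ch <- read_tsv(config$changes_tsv)$protein_change
    exchange <- exchange_matrix(ch)
    aa_tables <- list(type_by_group = variation_type_by_group(ch),
                      insertion_spectrum = insertion_spectrum(ch))
  }

  tests <- list(degenerate = FALSE)
  groups <- split(fraction_table$fraction, fraction_table$region_tag)
  if (nrow(ann_all) == 0L || sum(fraction_table$variant_count) == 0L) {
    tests$degenerate <- TRUE
  } else if (all(lengths(groups) >= 2L)) {
    tests$anova <- tryCatch({
      a <- wh(one_way_anova(groups))
      a$fit <- NULL
      a
    }, error = function(e) list(error = conditionMessage(e)))
    tests$tukey <- tryCatch(wh(tukey_hsd(groups)),
                            error = function(e)
                              list(error = conditionMessage(e)))
  }
  if (!is.null(aa_tables)) {
    tab <- aa_tables$type_by_group
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) >= 2L && ncol(tab) >= 2L) {
      tests$type_by_group_chisq <- wh(chi_square_homogeneity(tab))
    }
  }

  inputs <- unlist(config[names(config) %in%
                            c("proteins_fasta", "genome_fasta", "gff3",
                              "vcf", "changes_tsv")])
  manifest <- list(
    seed = seed,
    parameters = list(alpha = alpha, p0_floor = p0_floor,
                      maf_bin_edges = c(0.005, 0.01, 0.05),
                      splice_window_nt = 2L),
    input_digests = as.list(tools::md5sum(inputs)),
    n_clusters = nrow(clusters),
    n_variants = nrow(variants),
    n_warnings = n_warn)

  bundle <- list(clusters = clusters, mapped = mapped,
                 annotations = ann_all, fraction_table = fraction_table,
                 tallies = tallies, exchange = exchange,
                 aa_tables = aa_tables, tests = tests, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(clusters, file.path(out_dir, "clusters.tsv"))
    write_tsv(fraction_table, file.path(out_dir, "fraction_table.tsv"))
    write_tsv(ann_all, file.path(out_dir, "annotations.tsv"))
    if (!is.null(exchange)) {
      write_tsv(as.data.frame(exchange$counts),
                file.path(out_dir, "exchange_matrix.tsv"))
      write_tsv(data.frame(residue = names(exchange$loss),
                           loss = as.integer(exchange$loss),
                           gain = as.integer(exchange$gain)),
                file.path(out_dir, "gain_loss.tsv"))
    }
    report <- list(tallies = lapply(tallies, as.list),
                   tests = tests, manifest = manifest)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
    manifest$outputs <- list.files(out_dir)
    bundle$manifest <- manifest
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a
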