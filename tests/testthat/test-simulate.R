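test_that("configuration mixtures must sum to one", {
  cfg <- default_sim_config("negative")
  expect_s3_class(cfg, "SimulationConfig")
  cfg$variant_type_mix <- c(SNV = 0.9, deletion = 0.2, insertion = 0.1)
  expect_error(validate_sim_config(cfg), "variant_type_mix")
  cfg <- default_sim_config("positive")
  expect_equal(sum(cfg$maf_bin_mix), 1)
  expect_equal(unname(cfg$maf_bin_mix["lt_0.005"]), 0.85)
})

test_that("proteins with no planted cluster are a clean negative control", {
  cfg <- default_sim_config("negative")
  cfg$cluster_rate <- 0
  set.seed(51)
  hits <- 0L
  for (i in 1:40) {
    pr <- simulate_protein(cfg)
    expect_equal(nrow(pr$truth), 0L)
    hits <- hits + nrow(find_charge_clusters(pr$seq, "negative"))
  }
  expect_lte(hits, 4L)  # ~alpha-level discoveries only
})

test_that("planted clusters respect the definition and the length law", {
  cfg <- default_sim_config("negative")
  set.seed(52)
  lens <- integer(500)
  for (i in 1:500) {
    pr <- simulate_protein(cfg)
    tr <- pr$truth
    expect_equal(nrow(tr), 1L)
    lens[i] <- tr$length_aa
    seg <- strsplit(substr(pr$seq, tr$start_aa, tr$end_aa), "")[[1]]
    # no opposite charge inside; same-sign boundaries
    expect_false(any(seg %in% c("K", "R")))
    expect_true(seg[1] %in% c("D", "E"))
    expect_true(seg[length(seg)] %in% c("D", "E"))
  }
  expect_true(all(lens >= 20 & lens <= 75))
  # mean within 3 SE of the configured truncated normal's analytic mean
  # (closed form; +0.1 covers the integer rounding of lengths)
  mu <- cfg$cluster_length[["mean"]]; s <- cfg$cluster_length[["sd"]]
  a <- (20 - mu) / s; b <- (75 - mu) / s
  mu_trunc <- mu + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  se <- s / sqrt(500)
  expect_lt(abs(mean(lens) - mu_trunc), 3 * se + 0.1)
})

test_that("simulated gene models re-translate to their protein exactly", {
  cfg <- default_sim_config("negative")
  set.seed(53)
  for (i in 1:15) {
    pr <- simulate_protein(cfg)
    g <- simulate_gene_model(pr, cfg)
    cds <- spliced_cds(g$model, g$genome)
    p <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                            no.init.codon = TRUE))
    expect_identical(sub("\\*$", "", p), pr$seq)
    # truth exon span equals the mapped span
    m <- map_cluster(list(start_aa = g$truth$start_aa,
                          end_aa = g$truth$end_aa), g$model)
    expect_equal(m$exon_span, g$truth$exon_span)
    if (g$truth$exon_span == 1L) {
      expect_equal(m$context_regions$cluster_exonic$length_nt,
                   m$context_regions$cluster_exonic_plus_intronic$length_nt)
    }
  }
})

test_that("variant realization matches the genome and the planted law", {
  cfg <- default_sim_config("negative")
  set.seed(54)
  pr <- simulate_protein(cfg)
  g <- simulate_gene_model(pr, cfg)
  # zero density gives zero variants
  cfg0 <- cfg
  cfg0$variant_density[] <- 0
  expect_equal(nrow(simulate_variants(g, cfg0)$variants), 0L)
  # alleles always match the reference genome
  vs <- simulate_variants(g, cfg)
  for (i in seq_len(nrow(vs$variants))) {
    v <- vs$variants[i, ]
    expect_identical(substr(g$genome, v$pos, v$pos + nchar(v$ref) - 1L),
                     v$ref)
  }
  # realized MAF values fall in their planted bin
  spec <- !is.na(vs$variants$maf_EXAC)
  expect_identical(maf_bin(vs$variants$maf_EXAC[spec]),
                   vs$truth$true_bin_EXAC[spec])
  expect_true(all(vs$truth$true_bin_EXAC[!spec] == "unspecified"))
})

test_that("variant counts follow the configured binomial density", {
  cfg <- default_sim_config("negative")
  # single-exon gene so the cluster region has exactly one density
  cfg$exon_span_mix <- c(`1` = 1, `2` = 0, `3` = 0)
  cfg$extra_intron_prob <- 0
  set.seed(55)
  pr <- simulate_protein(cfg)
  g <- simulate_gene_model(pr, cfg)
  m <- map_cluster(list(start_aa = g$truth$start_aa,
                        end_aa = g$truth$end_aa), g$model)
  L <- m$context_regions$cluster_exonic$length_nt
  d <- cfg$variant_density["cluster_exonic"]
  counts <- vapply(1:300, function(i) {
    vs <- simulate_variants(g, cfg)
    nrow(variants_in_region(vs$variants,
                            m$context_regions$cluster_exonic$intervals))
  }, numeric(1))
  # overlap suppression removes a little mass; allow 3 SE plus that bias
  se <- sqrt(L * d * (1 - d)) / sqrt(300)
  expect_lt(abs(mean(counts) - L * d), 3 * se + 0.05 * L * d)
})

test_that("protein-change strings round-trip through the parser", {
  cfg <- default_sim_config("negative")
  set.seed(56)
  sim <- simulate_protein_changes(cfg, n = 300)
  for (i in seq_len(300)) {
    pc <- parse_protein_change(sim$changes[i])
    tr <- sim$truth[i, ]
    expect_equal(pc$kind, tr$kind)
    expect_equal(pc$position, tr$position)
    expect_equal(pc$ref_res, tr$ref_res)
    if (tr$kind == "insertion") {
      expect_equal(pc$inserted_seq, tr$inserted_seq)
    } else if (tr$kind %in% c("substitution", "synonymous")) {
      expect_equal(pc$alt_res, tr$alt_res)
    }
  }
  # all-substitution mixture parses as all substitutions
  cfg$change_category_mix <- c(substitution = 1, synonymous = 0,
                               deletion = 0, insertion = 0)
  sim <- simulate_protein_changes(cfg, n = 100)
  expect_true(all(vapply(sim$changes, function(s)
    parse_protein_change(s)$kind, character(1)) == "substitution"))
})

test_that("planted category mixtures are recovered within 3 SE", {
  cfg <- default_sim_config("negative")
  set.seed(57)
  sim <- simulate_protein_changes(cfg, n = 2000)
  for (k in names(cfg$change_category_mix)) {
    p <- cfg$change_category_mix[[k]]
    expect_true(within_3se(mean(sim$truth$kind == k), p, 2000))
  }
})

test_that("identical configuration and seed give byte-identical files", {
  cfg <- default_sim_config("negative")
  cfg$n_genes <- 3L
  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  suppressWarnings(simulate_cohort(cfg, seed = 99, out_dir = d1,
                                   n_changes = 50))
  suppressWarnings(simulate_cohort(cfg, seed = 99, out_dir = d2,
                                   n_changes = 50))
  for (f in list.files(d1)) {
    a <- readLines(file.path(d1, f)); b <- readLines(file.path(d2, f))
    # the VCF carries a fileDate line that tracks the wall clock
    a <- a[!grepl("^##fileDate", a)]; b <- b[!grepl("^##fileDate", b)]
    expect_identical(a, b)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted clusters are recovered by the detector at high recall", {
  cfg <- default_sim_config("negative")
  set.seed(58)
  n <- 200L
  recovered <- 0L
  for (i in seq_len(n)) {
    pr <- simulate_protein(cfg)
    tr <- pr$truth
    cl <- find_charge_clusters(pr$seq, "negative",
                               alpha = cfg$alpha, p0_floor = cfg$p0_floor)
    ov <- FALSE
    for (j in seq_len(nrow(cl))) {
      inter <- min(cl$end_aa[j], tr$end_aa) - max(cl$start_aa[j],
                                                  tr$start_aa) + 1L
      if (inter >= 0.5 * tr$length_aa) ov <- TRUE
    }
    if (ov) recovered <- recovered + 1L
  }
  expect_gte(recovered / n, 0.95)
})
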