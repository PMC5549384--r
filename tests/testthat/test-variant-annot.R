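test_that("allele pairs normalize and classify by length relation", {
  expect_equal(classify_variant_type("A", "G"), "SNV")
  expect_equal(classify_variant_type("A", "AGA"), "insertion")
  expect_equal(classify_variant_type("TTC", "T"), "deletion")
  expect_equal(classify_variant_type("AT", "GC"), "MNV")
  expect_error(classify_variant_type("AT", "TACG"), "classify")

  nm <- normalize_allele_pair(100L, "ATG", "GTG")
  expect_equal(nm, list(pos = 100L, ref = "A", alt = "G"))
  nm <- normalize_allele_pair(100L, "CAT", "CGT")
  expect_equal(nm, list(pos = 101L, ref = "A", alt = "G"))
  # padded deletion keeps its anchor
  nm <- normalize_allele_pair(100L, "TTC", "T")
  expect_equal(nm$ref, "TTC")
  expect_error(normalize_allele_pair(1L, "A", "A"), "differ")
})

test_that("region membership is inclusive and matches brute force", {
  v <- data.frame(pos = c(5L, 10L, 11L, 20L, 21L))
  iv <- data.frame(start = c(10L, 20L), end = c(11L, 20L))
  expect_equal(variants_in_region(v, iv)$pos, c(10L, 11L, 20L))
  expect_equal(nrow(variants_in_region(v, iv[0, ])), 0L)
  set.seed(21)
  for (rep in 1:10) {
    v <- data.frame(pos = sample.int(500, 80))
    iv <- data.frame(start = s <- sort(sample.int(480, 5)),
                     end = s + sample.int(20, 5))
    got <- variants_in_region(v, iv)$pos
    want <- v$pos[vapply(v$pos, function(p)
      any(p >= iv$start & p <= iv$end), logical(1))]
    expect_identical(got, want)
  }
})

test_that("MAF bins partition [0, 0.5] with half-open edges", {
  expect_equal(maf_bin(0.001), "lt_0.005")
  expect_equal(maf_bin(0.03), "0.01_to_0.05")
  expect_equal(maf_bin(0.005), "0.005_to_0.01")
  expect_equal(maf_bin(0.05), "ge_0.05")
  expect_equal(maf_bin(0), "lt_0.005")
  expect_equal(maf_bin(0.5), "ge_0.05")
  expect_equal(maf_bin(NA), "unspecified")
  expect_error(maf_bin(-0.1), "\\[0, 0.5\\]")
  expect_error(maf_bin(0.6), "\\[0, 0.5\\]")
  # every present frequency falls in exactly one bin
  set.seed(31)
  f <- runif(500, 0, 0.5)
  expect_false(any(maf_bin(f) == "unspecified"))
})

test_that("clinical labels collapse onto the two spectra", {
  expect_equal(clinical_class("Pathogenic"), "pathogenic_spectrum")
  expect_equal(clinical_class("Likely pathogenic"), "pathogenic_spectrum")
  expect_equal(clinical_class("probably pathogenic"), "pathogenic_spectrum")
  expect_equal(clinical_class("risk factor"), "pathogenic_spectrum")
  expect_equal(clinical_class("Benign"), "benign_spectrum")
  expect_equal(clinical_class("likely benign"), "benign_spectrum")
  expect_equal(clinical_class("Likely_benign"), "benign_spectrum")
  expect_equal(clinical_class("Uncertain significance"), "unspecified")
  expect_equal(clinical_class(NA), "unspecified")
})

test_that("hand-built codon cases call the documented consequences", {
  # protein MEK: ATG GAA AAA TAA on the plus strand
  g <- make_single_exon_gene("MEK")
  gm <- g$gm; genome <- g$genome
  # codon GAA third base A>G: still Glu
  p <- gm$gene_start + 5L
  mc <- molecular_consequence(list(pos = p, ref = "A", alt = "G"),
                              gm, genome)
  expect_equal(mc$consequence, "synonymous")
  # codon GAA first base G>A: Glu -> Lys
  p <- gm$gene_start + 3L
  mc <- molecular_consequence(list(pos = p, ref = "G", alt = "A"),
                              gm, genome)
  expect_equal(mc$consequence, "missense")
  expect_equal(mc$protein_change, "Glu2Lys")
  # codon CGA first base C>T: Arg -> Ter
  g2 <- make_single_exon_gene("MER")
  p <- g2$gm$gene_start + 6L
  mc <- molecular_consequence(list(pos = p, ref = "C", alt = "T"),
                              g2$gm, g2$genome)
  expect_equal(mc$consequence, "stop_gained")
  expect_equal(mc$protein_change, "Arg3Ter")
  # 1-nt deletion in the CDS: frameshift
  p <- gm$gene_start + 3L
  mc <- molecular_consequence(list(pos = p, ref = "GA", alt = "G"),
                              gm, genome)
  expect_equal(mc$consequence, "frameshift")
  # 3-nt deletion: inframe
  mc <- molecular_consequence(list(pos = p, ref = "GAAA", alt = "G"),
                              gm, genome)
  expect_equal(mc$consequence, "inframe_deletion")
  # stop lost at the terminator codon
  p <- gm$gene_start + 9L
  mc <- molecular_consequence(list(pos = p, ref = "T", alt = "C"),
                              gm, genome)
  expect_equal(mc$consequence, "stop_lost")
  # reference mismatch is an error
  expect_error(
    molecular_consequence(list(pos = gm$gene_start, ref = "C", alt = "T"),
                          gm, genome),
    "mismatch")
})

test_that("minus-strand codon cases complement the alt allele", {
  g <- make_single_exon_gene("MEK", strand = "-")
  gm <- g$gm
  # CDS position 4 (first base of the Glu codon) is the 4th-highest
  # genomic coordinate of the CDS
  map <- cds_genomic_map(gm)
  p <- map[4]
  ref <- substr(g$genome, p, p)  # complement of G = C
  expect_equal(ref, "C")
  mc <- molecular_consequence(list(pos = p, ref = "C", alt = "T"),
                              gm, g$genome)
  expect_equal(mc$consequence, "missense")
  expect_equal(mc$protein_change, "Glu2Lys")
})

test_that("splice-region and intronic calls use the 2 nt intron ends", {
  two3 <- data.frame(start = c(1001L, 2001L), end = c(1100L, 2101L))
  gm <- gene_model("g", "chr", "+", 901L, 2200L, exons = two3,
                   cds_exons = two3)
  genome <- paste(rep("A", 2300), collapse = "")
  for (p in c(1101L, 1102L, 1999L, 2000L)) {
    mc <- molecular_consequence(list(pos = p, ref = "A", alt = "G"),
                                gm, genome)
    expect_equal(mc$consequence, "splice_region")
  }
  mc <- molecular_consequence(list(pos = 1500L, ref = "A", alt = "G"),
                              gm, genome)
  expect_equal(mc$consequence, "intronic")
  # outside the exons and introns: non-coding
  mc <- molecular_consequence(list(pos = 950L, ref = "A", alt = "G"),
                              gm, genome)
  expect_equal(mc$consequence, "non_coding")
})

test_that("consequence caller agrees with translate-and-diff on random SNVs", {
  cfg <- default_sim_config("negative")
  set.seed(717)
  n_checked <- 0L
  for (rep in 1:6) {
    pr <- simulate_protein(cfg)
    g <- simulate_gene_model(pr, cfg)
    gm <- g$model
    vs <- simulate_variants(g, cfg)
    keep <- which(vs$truth$true_type == "SNV")
    keep <- sample(keep, min(30, length(keep)))
    for (i in keep) {
      v <- vs$variants[i, ]
      mc <- molecular_consequence(list(pos = v$pos, ref = v$ref,
                                       alt = v$alt), gm, g$genome)
      want <- oracle_snv_consequence(v$pos, v$ref, v$alt, gm, g$genome)
      if (mc$consequence == "splice_region" || is.na(want)) next
      expect_equal(mc$consequence, want)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 50L)
})

test_that("variant counts are additive over the exonic/intronic split", {
  cfg <- default_sim_config("negative")
  set.seed(818)
  for (rep in 1:8) {
    pr <- simulate_protein(cfg)
    g <- simulate_gene_model(pr, cfg)
    vs <- simulate_variants(g, cfg)
    tr <- g$truth
    m <- map_cluster(list(start_aa = tr$start_aa, end_aa = tr$end_aa),
                     g$model)
    n_ex <- nrow(variants_in_region(vs$variants,
                                    m$context_regions$cluster_exonic$intervals))
    span <- m$context_regions$cluster_exonic_plus_intronic$intervals
    n_span <- nrow(variants_in_region(vs$variants, span))
    # intronic remainder = span minus the exonic blocks
    b <- m$genomic_blocks
    all_pos <- span$start:span$end
    intron_pos <- all_pos[!vapply(all_pos, function(p)
      any(p >= b$start & p <= b$end), logical(1))]
    n_intron <- sum(vs$variants$pos %in% intron_pos)
    expect_equal(n_ex + n_intron, n_span)
  }
})

test_that("annotation rows carry consistent region tags and classifications", {
  cfg <- default_sim_config("negative")
  set.seed(919)
  pr <- simulate_protein(cfg)
  g <- simulate_gene_model(pr, cfg)
  vs <- simulate_variants(g, cfg)
  tr <- g$truth
  m <- map_cluster(list(start_aa = tr$start_aa, end_aa = tr$end_aa), g$model)
  ann <- annotate_variants(vs$variants, m, g$model, g$genome)
  expect_true(all(ann$region_tag %in% names(m$context_regions)))
  cc <- ann[ann$region_tag == "cluster_exonic", ]
  idx <- match(cc$pos, vs$truth$pos)
  expect_identical(cc$var_type, vs$truth$true_type[idx])
  expect_identical(cc$clinical_class, vs$truth$true_clinical[idx])
  expect_identical(cc$maf_bin_EXAC, vs$truth$true_bin_EXAC[idx])
})
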