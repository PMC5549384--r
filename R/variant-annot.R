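#' Normalize an allele pair to its minimal anchored representation
#'
#' Trims shared trailing then leading bases while keeping at least one base
#' in each allele (VCF-style anchoring), adjusting the position for every
#' leading base removed. dbSNP-style inputs vary in padding; typing and
#' consequence calling assume this minimal form.
#'
#' @param pos 1-based position of the first `ref` base.
#' @param ref,alt Allele strings.
#' @return List with `pos`, `ref`, `alt`.
#' @export
normalize_allele_pair <- function(pos, ref, alt) {
  stopifnot(nzchar(ref), nzchar(alt))
  if (ref == alt) stop("ref and alt alleles must differ", call. = FALSE)
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Classify a variant by its alleles
#'
#' Expects normalized alleles (see [normalize_allele_pair()]): equal
#' single bases give `SNV`; a ref that is a prefix of a longer alt gives
#' `insertion`; an alt that is a prefix of a longer ref gives `deletion`;
#' equal lengths above one give `MNV`.
#'
#' @param ref,alt Normalized allele strings.
#' @return One of `"SNV"`, `"insertion"`, `"deletion"`, `"MNV"`.
#' @examples
#' classify_variant_type("A", "G")
#' classify_variant_type("A", "AGA")
#' classify_variant_type("TTC", "T")
#' @export
classify_variant_type <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 1L && na == 1L) return("SNV")
  if (nr < na && substr(alt, 1L, nr) == ref) return("insertion")
  if (nr > na && substr(ref, 1L, na) == alt) return("deletion")
  if (nr == na) return("MNV")
  stop(sprintf("cannot classify allele pair %s>%s (not normalizable)",
               ref, alt), call. = FALSE)
}

#' Subset variants overlapping a region
#'
#' A variant belongs to a region when its position lies in any of the
#' region's 1-based inclusive intervals; input order is preserved.
#'
#' @param variants Data frame with at least a `pos` column.
#' @param intervals Data frame of intervals (`start`, `end`).
#' @return The matching rows of `variants`.
#' @export
variants_in_region <- function(variants, intervals) {
  if (nrow(intervals) == 0L || nrow(variants) == 0L) {
    return(variants[integer(0), , drop = FALSE])
  }
  q <- IRanges::IRanges(start = variants$pos, width = 1L)
  s <- IRanges::IRanges(start = intervals$start, end = intervals$end)
  hit <- IRanges::overlapsAny(q, s)
  variants[hit, , drop = FALSE]
}

#' Bin a minor allele frequency
#'
#' Four half-open bins partition `[0, 0.5]`: `[0, 0.005)`,
#' `[0.005, 0.01)`, `[0.01, 0.05)` and `[0.05, 0.5]`; variants in the
#' lowest bin are termed rare. An absent frequency maps to
#' `"unspecified"` and is excluded from bin proportions downstream.
#'
#' @param freq Numeric frequency in `[0, 0.5]`, or `NA` for absent.
#' @return One of `"lt_0.005"`, `"0.005_to_0.01"`, `"0.01_to_0.05"`,
#'   `"ge_0.05"`, `"unspecified"` (vectorized).
#' @export
maf_bin <- function(freq) {
  if (any(!is.na(freq) & (freq < 0 | freq > 0.5))) {
    stop("minor allele frequency must lie in [0, 0.5]", call. = FALSE)
  }
  bins <- c("lt_0.005", "0.005_to_0.01", "0.01_to_0.05", "ge_0.05")
  out <- bins[findInterval(freq, c(0, 0.005, 0.01, 0.05))]
  out[is.na(freq)] <- "unspecified"
  out
}

#' Collapse a clinical-significance label onto three classes
#'
#' Pathogenic, probably/likely pathogenic and risk-factor labels map to
#' the pathogenic spectrum; benign and likely benign to the benign
#' spectrum; anything else (uncertain, conflicting, absent) is
#' unspecified and excluded from class proportions downstream.
#'
#' @param raw Character vector of free-text labels; `NA` for absent.
#' @return Character vector in `{"pathogenic_spectrum",
#'   "benign_spectrum", "unspecified"}`.
#' @export
clinical_class <- function(raw) {
  x <- gsub("_", " ", tolower(trimws(as.character(raw))))
  out <- rep("unspecified", length(x))
  out[grepl("pathogenic|risk factor", x)] <- "pathogenic_spectrum"
  out[grepl("benign", x)] <- "benign_spectrum"
  out[is.na(raw) | x == ""] <- "unspecified"
  out
}

# CDS index of a genomic position (NA when non-coding)
.genomic_to_cds_index <- function(pos, gm) {
  match(pos, cds_genomic_map(gm))
}

# intron intervals of a gene model (between consecutive exons)
.introns <- function(gm) {
  ex <- gm$exons
  if (nrow(ex) < 2L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
}

.in_intervals <- function(pos, iv) {
  any(pos >= iv$start & pos <= iv$end)
}

#' Molecular consequence of a variant on a gene model
#'
#' Calls a single consequence per variant using a severity precedence:
#' splice_region > stop_gained > stop_lost > frameshift > inframe >
#' missense > synonymous. Coding SNVs are resolved by mutating the
#' affected codon and translating both versions; indels are frameshift
#' when the length change is not a multiple of three, inframe otherwise.
#' The splice region is the 2 nt canonical donor/acceptor at each intron
#' end. Positions inside an intron but outside the splice region are
#' intronic; exonic positions outside the CDS are non-coding.
#'
#' @param variant List or one-row data frame with `pos`, `ref`, `alt`
#'   (normalized).
#' @param gm A `GeneModel`.
#' @param genome Chromosome sequence (string or `DNAString`).
#' @return List with `consequence` and `protein_change` (an HGVS.p-style
#'   short string, or `NA` when not applicable).
#' @export
molecular_consequence <- function(variant, gm, genome) {
  genome <- as.character(genome)
  pos <- as.integer(variant$pos); ref <- variant$ref; alt <- variant$alt
  obs <- substr(genome, pos, pos + nchar(ref) - 1L)
  if (obs != ref) {
    stop(sprintf("reference mismatch at %s:%d (expected %s, genome has %s)",
                 gm$chrom, pos, ref, obs), call. = FALSE)
  }
  affected <- pos:(pos + max(nchar(ref), 1L) - 1L)

  intr <- .introns(gm)
  splice <- logical(1)
  if (nrow(intr) > 0L) {
    sp <- rbind(data.frame(start = intr$start, end = intr$start + 1L),
                data.frame(start = intr$end - 1L, end = intr$end))
    splice <- any(vapply(affected, .in_intervals, logical(1), iv = sp))
  }
  if (isTRUE(splice)) return(list(consequence = "splice_region",
                                  protein_change = NA_character_))

  cds_map <- cds_genomic_map(gm)
  cds_idx <- match(affected, cds_map)
  in_cds <- !all(is.na(cds_idx))
  vt <- classify_variant_type(ref, alt)

  if (vt %in% c("insertion", "deletion")) {
    if (!in_cds && vt == "insertion") {
      # anchored insertion: the new bases land after `pos`
      in_cds <- !is.na(match(pos, cds_map))
    }
    if (!in_cds) {
      return(list(consequence = .noncoding_tag(affected, gm, intr),
                  protein_change = NA_character_))
    }
    delta <- abs(nchar(ref) - nchar(alt))
    cons <- if (delta %% 3L != 0L) "frameshift"
            else if (vt == "insertion") "inframe_insertion"
            else "inframe_deletion"
    return(list(consequence = cons, protein_change = NA_character_))
  }

  if (!in_cds) {
    return(list(consequence = .noncoding_tag(affected, gm, intr),
                protein_change = NA_character_))
  }

  # SNV or MNV within the CDS: splice in the change and translate
  cds <- spliced_cds(gm, genome)
  new_cds <- cds
  for (i in seq_along(affected)) {
    j <- cds_idx[i]
    if (is.na(j)) next
    base <- substr(alt, i, i)
    if (gm$strand == "-") {
      base <- as.character(
        Biostrings::complement(Biostrings::DNAString(base)))
    }
    substr(new_cds, j, j) <- base
  }
  codons <- unique((stats::na.omit(cds_idx) - 1L) %/% 3L + 1L)
  ref_aa <- .translate_codons(cds, codons)
  alt_aa <- .translate_codons(new_cds, codons)
  chg <- which(ref_aa != alt_aa)
  if (length(chg) == 0L) {
    aa <- ref_aa[1]; p <- codons[1]
    return(list(consequence = "synonymous",
                protein_change = .one_to_three(aa) %+% p %+% .one_to_three(aa)))
  }
  i <- chg[1]
  pchg <- .one_to_three(ref_aa[i]) %+% codons[i] %+% .one_to_three(alt_aa[i])
  cons <- if (alt_aa[i] == "*") "stop_gained"
          else if (ref_aa[i] == "*") "stop_lost"
          else "missense"
  list(consequence = cons, protein_change = pchg)
}

.noncoding_tag <- function(affected, gm, intr) {
  if (nrow(intr) > 0L &&
      any(vapply(affected, .in_intervals, logical(1), iv = intr))) {
    "intronic"
  } else {
    "non_coding"
  }
}

.translate_codons <- function(cds, codons) {
  vapply(codons, function(ci) {
    cod <- substr(cds, 3L * ci - 2L, 3L * ci)
    unname(Biostrings::GENETIC_CODE[cod])
  }, character(1))
}

.one_to_three <- function(aa) {
  if (aa == "*") return("Ter")
  unname(Biostrings::AMINO_ACID_CODE[aa])
}

#' Annotate a variant set against a mapped cluster
#'
#' Produces one row per (variant, region) pair over the four nested
#' context regions of a mapped cluster, carrying the variant's type,
#' molecular consequence, clinical class and per-source MAF bin.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   and optionally `clinical_raw`, `maf_1000G`, `maf_ESP`, `maf_EXAC`.
#' @param mapped A `MappedCluster`.
#' @param gm The matching `GeneModel`.
#' @param genome Chromosome sequence.
#' @return Data frame of annotations; zero rows when nothing overlaps.
#' @export
annotate_variants <- function(variants, mapped, gm, genome) {
  variants <- variants[variants$chrom == gm$chrom, , drop = FALSE]
  out <- list()
  for (tag in names(mapped$context_regions)) {
    iv <- mapped$context_regions[[tag]]$intervals
    sub <- variants_in_region(variants, iv)
    if (nrow(sub) == 0L) next
    ann <- lapply(seq_len(nrow(sub)), function(i) {
      v <- sub[i, ]
      nm <- normalize_allele_pair(v$pos, v$ref, v$alt)
      mc <- molecular_consequence(list(pos = nm$pos, ref = nm$ref,
                                       alt = nm$alt), gm, genome)
      data.frame(
        region_tag = tag, chrom = v$chrom, pos = v$pos,
        ref = v$ref, alt = v$alt,
        var_type = classify_variant_type(nm$ref, nm$alt),
        consequence = mc$consequence,
        protein_change = mc$protein_change,
        clinical_class = clinical_class(
          if ("clinical_raw" %in% names(v)) v$clinical_raw else NA),
        maf_bin_1000G = maf_bin(
          if ("maf_1000G" %in% names(v)) v$maf_1000G else NA),
        maf_bin_ESP = maf_bin(
          if ("maf_ESP" %in% names(v)) v$maf_ESP else NA),
        maf_bin_EXAC = maf_bin(
          if ("maf_EXAC" %in% names(v)) v$maf_EXAC else NA),
        stringsAsFactors = FALSE)
    })
    out[[tag]] <- do.call(rbind, ann)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(region_tag = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      var_type = character(), consequence = character(),
                      protein_change = character(),
                      clinical_class = character(),
                      maf_bin_1000G = character(), maf_bin_ESP = character(),
                      maf_bin_EXAC = character(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
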