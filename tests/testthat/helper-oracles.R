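# Independent brute-force oracles and random-input generators shared by
# the test files. Each oracle re-derives the expected result from first
# principles, never through the code path it checks.

RES20 <- names(Biostrings::AMINO_ACID_CODE)[1:20]

random_protein <- function(n, charge_freq = 0.1) {
  p <- stats::setNames(rep((1 - charge_freq) / 16, 20), RES20)
  p[c("D", "E", "K", "R")] <- charge_freq / 4
  paste(sample(RES20, n, TRUE, prob = p), collapse = "")
}

# sequence enriched for one sign so significant clusters actually occur
biased_protein <- function(n, sign, same = 0.25, opp = 0.04) {
  p <- stats::setNames(rep((1 - same - opp) / 16, 20), RES20)
  same_pool <- if (sign == "positive") c("K", "R") else c("D", "E")
  opp_pool <- if (sign == "positive") c("D", "E") else c("K", "R")
  p[same_pool] <- same / 2
  p[opp_pool] <- opp / 2
  paste(sample(RES20, n, TRUE, prob = p), collapse = "")
}

charge_of <- function(a) {
  if (a %in% c("D", "E")) -1L else if (a %in% c("K", "R")) 1L else 0L
}

# oracle 1: every substring checked directly against the window definition
oracle_windows <- function(seq, sign, min_len = 20L, max_len = 75L) {
  aa <- strsplit(seq, "")[[1]]
  ch <- vapply(aa, charge_of, integer(1))
  sv <- if (sign == "positive") 1L else -1L
  out <- list()
  n <- length(aa)
  for (s in seq_len(n)) {
    for (e in s:min(n, s + max_len - 1L)) {
      len <- e - s + 1L
      if (len < min_len) next
      seg <- ch[s:e]
      if (seg[1] == sv && seg[len] == sv && !any(seg == -sv)) {
        out[[length(out) + 1L]] <- data.frame(
          start = s, end = e, length = len, charged_count = sum(seg == sv))
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    data.frame(start = integer(), end = integer(), length = integer(),
               charged_count = integer())
  } else {
    res[order(res$start, res$end), , drop = FALSE]
  }
}

# oracle 2: significance filter + iterative smallest-p/longest/leftmost
# disjoint selection, written as a plain loop over the candidate list
oracle_clusters <- function(seq, sign, alpha = 0.01, p0_floor = 0.05) {
  win <- oracle_windows(seq, sign)
  if (nrow(win) == 0L) return(win)
  ch <- vapply(strsplit(seq, "")[[1]], charge_of, integer(1))
  sv <- if (sign == "positive") 1L else -1L
  p0 <- max(sum(ch == sv) / length(ch), p0_floor)
  win$p_value <- vapply(seq_len(nrow(win)), function(i) {
    sum(stats::dbinom(win$charged_count[i]:win$length[i], win$length[i], p0))
  }, numeric(1))
  win <- win[win$p_value <= alpha, , drop = FALSE]
  chosen <- win[0, ]
  while (nrow(win) > 0L) {
    best <- which(win$p_value == min(win$p_value))
    best <- best[win$length[best] == max(win$length[best])]
    best <- best[which.min(win$start[best])]
    chosen <- rbind(chosen, win[best, ])
    ov <- win$start <= win$end[best] & win$end >= win$start[best]
    win <- win[!ov, , drop = FALSE]
  }
  chosen[order(chosen$start), , drop = FALSE]
}

# random gene model with 1-10 exons on either strand, plus its genome;
# exon/CDS structure built positionally, independent of the simulator
random_gene_model <- function(n_aa = 40L, max_exons = 10L) {
  cds_len <- 3L * (n_aa + 1L)
  n_cuts <- sample(0:(max_exons - 1L), 1L)
  cuts <- sort(sample(seq_len(cds_len - 1L), min(n_cuts, cds_len - 1L)))
  strand <- sample(c("+", "-"), 1L)
  bases <- c("A", "C", "G", "T")
  piece_s <- c(1L, cuts + 1L); piece_e <- c(cuts, cds_len)
  pos <- 101L
  ex <- list()
  for (i in seq_along(piece_s)) {
    w <- piece_e[i] - piece_s[i] + 1L
    ex[[i]] <- c(pos, pos + w - 1L)
    pos <- pos + w + sample(20:80, 1L)  # intron
  }
  ex <- do.call(rbind, ex)
  exons <- data.frame(start = ex[, 1], end = ex[, 2])
  genome_len <- max(exons$end) + 100L
  genome <- paste(sample(bases, genome_len, TRUE), collapse = "")
  gm <- gene_model("g", "chr", strand, gene_start = 91L,
                   gene_end = max(exons$end) + 10L,
                   exons = exons, cds_exons = exons)
  list(gm = gm, genome = genome, n_aa = n_aa)
}

# per-base exon map computed by naive enumeration
oracle_cds_map <- function(gm) {
  pos <- integer(0)
  for (i in seq_len(nrow(gm$cds_exons))) {
    pos <- c(pos, gm$cds_exons$start[i]:gm$cds_exons$end[i])
  }
  if (gm$strand == "-") rev(pos) else pos
}

# translate-and-diff consequence oracle for SNVs: apply the variant to
# the chromosome, resplice, translate, compare proteins
oracle_snv_consequence <- function(pos, ref, alt, gm, genome) {
  g2 <- genome
  substr(g2, pos, pos) <- alt
  cds1 <- spliced_cds(gm, genome); cds2 <- spliced_cds(gm, g2)
  if (cds1 == cds2) return(NA_character_)
  p1 <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(cds1), no.init.codon = TRUE)), "")[[1]]
  p2 <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(cds2), no.init.codon = TRUE)), "")[[1]]
  d <- which(p1 != p2)
  if (length(d) == 0L) return("synonymous")
  d <- d[1]
  if (p2[d] == "*") "stop_gained" else if (p1[d] == "*") "stop_lost"
  else "missense"
}

# direct-formula chi-square
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# direct sums-of-squares one-way F
oracle_anova_F <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1L
  dfw <- length(all) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# tolerance for a planted binomial proportion: 3 standard errors
within_3se <- function(p_hat, p, n) {
  abs(p_hat - p) <= 3 * sqrt(p * (1 - p) / n)
}

make_single_exon_gene <- function(protein = "MEK", chrom = "chr1",
                                  strand = "+", offset = 1000L) {
  # deterministic single-exon gene for hand-computed consequence cases
  codons <- c(M = "ATG", E = "GAA", K = "AAA", R = "CGA", L = "CTT",
              A = "GCC", G = "GGG", S = "TCT")
  aa <- strsplit(protein, "")[[1]]
  cds <- paste(c(codons[aa], "TAA"), collapse = "")
  if (strand == "-") {
    cds_genomic <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  } else {
    cds_genomic <- cds
  }
  genome <- paste0(strrep("T", offset), cds_genomic, strrep("T", 50))
  gm <- gene_model("g1", chrom, strand, offset + 1L,
                   offset + nchar(cds),
                   exons = data.frame(start = offset + 1L,
                                      end = offset + nchar(cds)),
                   cds_exons = data.frame(start = offset + 1L,
                                          end = offset + nchar(cds)))
  list(gm = gm, genome = genome, cds = cds)
}
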