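#' Charge of a single amino-acid residue
#'
#' Asp (D) and Glu (E) carry a negative charge, Lys (K) and Arg (R) a
#' positive one; every other standard residue is neutral. Non-standard or
#' ambiguity codes (B, Z, X, U, `*`, ...) score 0 so that they never block a
#' candidate window; each such residue triggers one warning so the input can
#' be audited.
#'
#' @param aa Character vector of one-letter, uppercase residue codes.
#' @return Integer vector in `{-1, 0, +1}`, same length as `aa`.
#' @examples
#' residue_charge(c("E", "R", "H", "A"))
#' @export
residue_charge <- function(aa) {
  stopifnot(is.character(aa), all(nchar(aa) == 1L))
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  odd <- setdiff(unique(aa), std)
  if (length(odd) > 0L) {
    warning("non-standard residue code(s) scored as uncharged: ",
            paste(odd, collapse = ", "), call. = FALSE)
  }
  ifelse(aa %in% c("D", "E"), -1L, ifelse(aa %in% c("K", "R"), 1L, 0L))
}

.sign_value <- function(sign) {
  sign <- match.arg(sign, c("positive", "negative"))
  if (sign == "positive") 1L else -1L
}

.charge_vector <- function(seq) {
  residue_charge(strsplit(toupper(seq), "")[[1]])
}

#' Enumerate candidate charge-cluster windows
#'
#' Returns every interval of `seq` whose length lies in
#' `[min_len, max_len]`, contains no residue of the opposite charge, and
#' both starts and ends on a residue of the requested sign (so boundaries
#' are tight, never padded by uncharged flanks). Uncharged residues may
#' interrupt the window freely.
#'
#' @param seq Protein sequence (single string of one-letter codes).
#' @param sign `"positive"` or `"negative"`.
#' @param min_len,max_len Window length bounds in residues (defaults 20, 75).
#' @return A data.frame with columns `start`, `end` (1-based inclusive),
#'   `length`, `charged_count`; zero rows when no window qualifies.
#' @export
candidate_windows <- function(seq, sign, min_len = 20L, max_len = 75L) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq),
            min_len >= 1L, max_len >= min_len)
  sv <- .sign_value(sign)
  ch <- .charge_vector(seq)
  n <- length(ch)
  empty <- data.frame(start = integer(), end = integer(),
                      length = integer(), charged_count = integer())
  if (n < min_len) return(empty)

  same <- which(ch == sv)
  if (length(same) == 0L) return(empty)
  # prefix counts of opposite-sign and same-sign residues
  opp_cum <- cumsum(ch == -sv)
  same_cum <- cumsum(ch == sv)
  res <- vector("list", length(same))
  for (i in seq_along(same)) {
    s <- same[i]
    ends <- same[same >= s + min_len - 1L & same <= min(n, s + max_len - 1L)]
    if (length(ends) == 0L) next
    opp_in <- opp_cum[ends] - if (s > 1L) opp_cum[s - 1L] else 0L
    ends <- ends[opp_in == 0L]
    if (length(ends) == 0L) next
    k <- same_cum[ends] - if (s > 1L) same_cum[s - 1L] else 0L
    res[[i]] <- data.frame(start = s, end = ends,
                           length = ends - s + 1L, charged_count = k)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) empty else {
    rownames(out) <- NULL
    out[order(out$start, out$end), , drop = FALSE]
  }
}

#' Binomial tail probability of a window's charge density
#'
#' Significance of observing `k` or more same-sign residues in a window of
#' `w` residues when each position independently carries that sign with
#' background probability `p0`: `P(X >= k)` for `X ~ Binomial(w, p0)`.
#'
#' @param k Observed same-sign residue count, `0 <= k <= w`.
#' @param w Window length in residues.
#' @param p0 Background same-sign frequency, strictly inside (0, 1).
#' @return Upper-tail probability.
#' @export
window_pvalue <- function(k, w, p0) {
  if (any(p0 <= 0) || any(p0 >= 1)) {
    stop("`p0` must lie strictly inside (0, 1)", call. = FALSE)
  }
  stopifnot(all(k >= 0), all(k <= w))
  stats::pbinom(k - 1, size = w, prob = p0, lower.tail = FALSE)
}

#' Detect significant, disjoint charge clusters in one protein
#'
#' Enumerates all candidate windows of the requested sign (20-75 residues,
#' free of opposite charge, charged boundaries), scores each by the
#' binomial-tail significance of its same-sign residue count against the
#' protein-wide background frequency of that sign (floored at `p0_floor` so
#' that charge-poor proteins are not trivially significant), keeps windows
#' with p-value at most `alpha`, and greedily selects a disjoint set:
#' repeatedly accept the window with the smallest p-value (ties broken by
#' longest, then leftmost) and drop everything overlapping it.
#'
#' @param seq Protein sequence (single string).
#' @param sign `"positive"` or `"negative"`.
#' @param alpha Significance level for a window (default 0.01).
#' @param p0_floor Lower bound on the background frequency (default 0.05).
#' @param protein_id Identifier copied into the output (default `"protein"`).
#' @param min_len,max_len Cluster length bounds (defaults 20, 75).
#' @return A data.frame of clusters sorted by `start_aa` with columns
#'   `protein_id`, `sign`, `start_aa`, `end_aa`, `length_aa`,
#'   `charged_count`, `p_value`; zero rows when nothing qualifies.
#' @examples
#' find_charge_clusters(strrep("A", 40) %+% strrep("E", 25) %+% strrep("A", 40),
#'                      "negative")
#' @export
find_charge_clusters <- function(seq, sign, alpha = 0.01, p0_floor = 0.05,
                                 protein_id = "protein",
                                 min_len = 20L, max_len = 75L) {
  sign <- match.arg(sign, c("positive", "negative"))
  cols <- c("protein_id", "sign", "start_aa", "end_aa", "length_aa",
            "charged_count", "p_value")
  empty <- stats::setNames(
    data.frame(character(), character(), integer(), integer(), integer(),
               integer(), numeric()), cols)
  win <- candidate_windows(seq, sign, min_len, max_len)
  if (nrow(win) == 0L) return(empty)

  ch <- .charge_vector(seq)
  p0 <- max(mean(ch == .sign_value(sign)), p0_floor)
  win$p_value <- window_pvalue(win$charged_count, win$length, p0)
  win <- win[win$p_value <= alpha, , drop = FALSE]
  if (nrow(win) == 0L) return(empty)

  picked <- greedy_disjoint(win)
  data.frame(protein_id = protein_id, sign = sign,
             start_aa = picked$start, end_aa = picked$end,
             length_aa = picked$length, charged_count = picked$charged_count,
             p_value = picked$p_value, stringsAsFactors = FALSE)
}

# Greedy disjoint selection over scored windows: smallest p-value first,
# ties broken by longest then leftmost; overlapping windows are discarded.
greedy_disjoint <- function(win) {
  win <- win[order(win$p_value, -win$length, win$start), , drop = FALSE]
  keep <- logical(nrow(win))
  blocked_s <- integer(0)
  blocked_e <- integer(0)
  for (i in seq_len(nrow(win))) {
    s <- win$start[i]; e <- win$end[i]
    if (!any(s <= blocked_e & e >= blocked_s)) {
      keep[i] <- TRUE
      blocked_s <- c(blocked_s, s)
      blocked_e <- c(blocked_e, e)
    }
  }
  out <- win[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Detect charge clusters in a set of protein sequences
#'
#' Runs [find_charge_clusters()] for both signs over every record of a
#' protein set and binds the results.
#'
#' @param proteins Named character vector of sequences, or an
#'   `Biostrings::AAStringSet`.
#' @inheritParams find_charge_clusters
#' @return Combined cluster data.frame (see [find_charge_clusters()]).
#' @export
detect_charge_clusters <- function(proteins, alpha = 0.01, p0_floor = 0.05,
                                   min_len = 20L, max_len = 75L) {
  if (methods::is(proteins, "AAStringSet")) {
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  }
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  out <- lapply(names(proteins), function(id) {
    rbind(
      find_charge_clusters(proteins[[id]], "negative", alpha, p0_floor, id,
                           min_len, max_len),
      find_charge_clusters(proteins[[id]], "positive", alpha, p0_floor, id,
                           min_len, max_len)
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname grapes-plus-grapes
#' @name %+%
#' @title String concatenation
#' @description Infix shorthand for `paste0`.
#' @param a,b Character vectors.
#' @return `paste0(a, b)`.
#' @export
`%+%` <- function(a, b) paste0(a, b)
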