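#' Physicochemical group of an amino acid
#'
#' The 20 standard residues partition into four side-chain groups:
#' hydrophobic (Ala, Val, Leu, Ile, Met, Phe, Trp, Pro), polar (Gly, Ser,
#' Thr, Cys, Tyr, Asn, Gln, His), acidic (Glu, Asp) and basic (Lys, Arg).
#' The stop symbol and non-standard codes carry no group and are excluded
#' from the exchange matrix (tracked in side tallies instead).
#'
#' @param aa One-letter residue codes (vectorized); 3-letter codes are
#'   accepted and normalized.
#' @return Character vector in `{"hydrophobic", "polar", "acidic",
#'   "basic"}`, `NA` for ungrouped symbols.
#' @examples
#' aa_group(c("P", "C", "D", "K"))
#' @export
aa_group <- function(aa) {
  aa <- vapply(aa, normalize_residue, character(1), USE.NAMES = FALSE)
  groups <- c(
    stats::setNames(rep("hydrophobic", 8), strsplit("AVLIMFWP", "")[[1]]),
    stats::setNames(rep("polar", 8), strsplit("GSTCYNQH", "")[[1]]),
    stats::setNames(rep("acidic", 2), c("E", "D")),
    stats::setNames(rep("basic", 2), c("K", "R")))
  unname(groups[aa])
}

AA_GROUPS <- c("hydrophobic", "polar", "acidic", "basic")
CHANGE_KINDS <- c("substitution", "synonymous", "insertion", "deletion",
                  "frameshift", "stop_gained", "stop_lost")

#' Normalize a residue code to one letter
#'
#' Accepts one-letter and three-letter codes plus `Ter`/`*` for the stop
#' symbol.
#'
#' @param res Residue code.
#' @return One-letter code (`"*"` for stop).
#' @export
normalize_residue <- function(res) {
  res <- as.character(res)
  if (nchar(res) == 1L) return(toupper(res))
  res3 <- paste0(toupper(substr(res, 1, 1)), tolower(substr(res, 2, 3)))
  if (res3 == "Ter") return("*")
  code <- Biostrings::AMINO_ACID_CODE
  hit <- names(code)[match(res3, code)]
  if (is.na(hit)) stop("unknown residue code: ", res, call. = FALSE)
  hit
}

# split a run of concatenated 3-letter codes ("GluGluLys") or return a
# 1-letter string as-is
.residue_run <- function(txt) {
  if (grepl("^[A-Z][a-z]{2}([A-Z][a-z]{2})*$", txt)) {
    codes <- substring(txt, seq(1, nchar(txt) - 2, 3),
                       seq(3, nchar(txt), 3))
    paste(vapply(codes, normalize_residue, character(1)), collapse = "")
  } else if (grepl("^[A-Z]+$", txt)) {
    txt
  } else {
    stop("cannot parse residue run: ", txt, call. = FALSE)
  }
}

#' Parse an HGVS.p-style protein-change string
#'
#' Recognized short forms (3-letter or 1-letter residue codes):
#' `Glu10Lys` (substitution), `Glu10Glu` or `Glu10=` (synonymous),
#' `Arg1024Ter` / `Glu10*` (stop gained), `Ter120Gln` (stop lost),
#' `Glu1294Argfs` / `Glu10fs` (frameshift), `Glu10del` (single-residue
#' deletion), `Glu10dup` (duplication, parsed as a length-1 insertion)
#' and `Glu10_Lys11insGluGlu` (insertion between two residues).
#'
#' @param text One change string.
#' @return An object of class `ProteinChange`: list with `position`,
#'   `ref_res`, `alt_res` (1-letter), `kind`, `inserted_len`,
#'   `inserted_seq`.
#' @examples
#' parse_protein_change("Glu1294Argfs")
#' parse_protein_change("Arg1024Ter")
#' parse_protein_change("Glu10Lys")
#' @export
parse_protein_change <- function(text) {
  text <- trimws(text)
  aa3 <- "[A-Z][a-z]{2}"
  aa1 <- "[A-Z]"
  aa <- sprintf("(%s|%s)", aa3, aa1)
  mk <- function(kind, position, ref = NA, alt = NA,
                 inserted_seq = NA_character_) {
    ilen <- if (!is.na(inserted_seq)) nchar(inserted_seq) else 0L
    structure(list(position = as.integer(position),
                   ref_res = if (is.na(ref)) NA_character_
                             else normalize_residue(ref),
                   alt_res = if (is.na(alt)) NA_character_
                             else normalize_residue(alt),
                   kind = kind, inserted_len = ilen,
                   inserted_seq = inserted_seq),
              class = "ProteinChange")
  }
  # insertion: Ref#_Ref#ins<run>
  m <- regmatches(text, regexec(
    sprintf("^%s(\\d+)_%s(\\d+)ins([A-Za-z]+)$", aa, aa), text))[[1]]
  if (length(m)) {
    run <- .residue_run(m[6])
    return(mk("insertion", m[3], ref = m[2], inserted_seq = run))
  }
  m <- regmatches(text, regexec(
    sprintf("^%s(\\d+)dup$", aa), text))[[1]]
  if (length(m)) {
    r <- normalize_residue(m[2])
    return(mk("insertion", m[3], ref = m[2], inserted_seq = r))
  }
  m <- regmatches(text, regexec(sprintf("^%s(\\d+)del$", aa), text))[[1]]
  if (length(m)) return(mk("deletion", m[3], ref = m[2]))
  m <- regmatches(text, regexec(
    sprintf("^%s(\\d+)%s?fs", aa, aa), text))[[1]]
  if (length(m)) return(mk("frameshift", m[3], ref = m[2]))
  m <- regmatches(text, regexec(
    sprintf("^%s(\\d+)(Ter|\\*)$", aa), text))[[1]]
  if (length(m)) return(mk("stop_gained", m[3], ref = m[2], alt = "Ter"))
  m <- regmatches(text, regexec(
    sprintf("^(Ter|\\*)(\\d+)%s$", aa), text))[[1]]
  if (length(m)) return(mk("stop_lost", m[3], ref = "Ter", alt = m[4]))
  m <- regmatches(text, regexec(sprintf("^%s(\\d+)=$", aa), text))[[1]]
  if (length(m)) return(mk("synonymous", m[3], ref = m[2], alt = m[2]))
  m <- regmatches(text, regexec(
    sprintf("^%s(\\d+)%s$", aa, aa), text))[[1]]
  if (length(m)) {
    ref <- normalize_residue(m[2]); alt <- normalize_residue(m[4])
    kind <- if (ref == alt) "synonymous" else "substitution"
    return(mk(kind, m[3], ref = m[2], alt = m[4]))
  }
  stop("cannot parse protein change: '", text, "'", call. = FALSE)
}

#' @export
print.ProteinChange <- function(x, ...) {
  cat(sprintf("ProteinChange: %s at %d (%s>%s)\n", x$kind, x$position,
              x$ref_res, if (x$kind == "insertion") x$inserted_seq
                         else x$alt_res))
  invisible(x)
}

.parse_changes <- function(changes) {
  if (is.character(changes)) changes <- lapply(changes, parse_protein_change)
  if (methods::is(changes, "ProteinChange")) changes <- list(changes)
  changes
}

#' Amino-acid group exchange matrix
#'
#' Tallies non-synonymous single-residue substitutions into a 4x4 matrix
#' of source group (rows) by destination group (columns), together with
#' per-residue loss (substituted away) and gain (substituted to) vectors.
#' Synonymous changes, indels, frameshifts and stop-involving
#' substitutions carry no group pair and are reported as side tallies.
#'
#' @param changes Character vector of change strings, or a list of
#'   `ProteinChange` objects.
#' @return List of class `ExchangeMatrix`: `counts` (4x4 matrix), `loss`
#'   and `gain` (named counts over the 20 residues), `n_substitutions`,
#'   and `side_tallies` (named counts per excluded kind).
#' @export
exchange_matrix <- function(changes) {
  changes <- .parse_changes(changes)
  res20 <- names(Biostrings::AMINO_ACID_CODE)[1:20]
  counts <- matrix(0L, 4, 4, dimnames = list(AA_GROUPS, AA_GROUPS))
  loss <- stats::setNames(integer(20), res20)
  gain <- stats::setNames(integer(20), res20)
  side <- stats::setNames(integer(length(CHANGE_KINDS)), CHANGE_KINDS)
  side["stop_involving"] <- 0L
  n_sub <- 0L
  for (ch in changes) {
    if (ch$kind == "substitution") {
      if (ch$ref_res == "*" || ch$alt_res == "*") {
        side["stop_involving"] <- side["stop_involving"] + 1L
        next
      }
      g1 <- aa_group(ch$ref_res); g2 <- aa_group(ch$alt_res)
      counts[g1, g2] <- counts[g1, g2] + 1L
      loss[ch$ref_res] <- loss[ch$ref_res] + 1L
      gain[ch$alt_res] <- gain[ch$alt_res] + 1L
      n_sub <- n_sub + 1L
    } else {
      side[ch$kind] <- side[ch$kind] + 1L
    }
  }
  side <- side[side > 0L | names(side) == "stop_involving"]
  structure(list(counts = counts, loss = loss, gain = gain,
                 n_substitutions = n_sub, side_tallies = side),
            class = "ExchangeMatrix")
}

#' @export
print.ExchangeMatrix <- function(x, ...) {
  cat(sprintf("ExchangeMatrix: %d substitutions\n", x$n_substitutions))
  print(x$counts)
  invisible(x)
}

#' Variation types by amino-acid group
#'
#' Contingency table of the four residue groups (rows) against the four
#' variation types (columns: substitution, synonymous, insertion,
#' deletion), suitable as chi-square input. Substitution, synonymous and
#' deletion records are attributed to the affected residue's group;
#' insertions contribute one count per inserted residue, attributed to
#' that residue's group. Frameshift and stop-involving records are
#' excluded (no residue group).
#'
#' @inheritParams exchange_matrix
#' @return 4x4 integer matrix.
#' @export
variation_type_by_group <- function(changes) {
  changes <- .parse_changes(changes)
  types <- c("substitution", "synonymous", "insertion", "deletion")
  tab <- matrix(0L, 4, 4, dimnames = list(AA_GROUPS, types))
  for (ch in changes) {
    if (ch$kind %in% c("substitution", "synonymous", "deletion")) {
      if (is.na(ch$ref_res) || ch$ref_res == "*") next
      if (ch$kind == "substitution" && ch$alt_res == "*") next
      g <- aa_group(ch$ref_res)
      tab[g, ch$kind] <- tab[g, ch$kind] + 1L
    } else if (ch$kind == "insertion") {
      for (r in strsplit(ch$inserted_seq, "")[[1]]) {
        g <- aa_group(r)
        if (!is.na(g)) tab[g, "insertion"] <- tab[g, "insertion"] + 1L
      }
    }
  }
  tab
}

#' Insertion length spectrum
#'
#' Per-length totals of inserted-residue runs (lengths 1..12, longer runs
#' pooled into `"13+"`) and the group composition of the inserted
#' residues at each length.
#'
#' @inheritParams exchange_matrix
#' @return List with `totals` (named counts by length) and `by_group`
#'   (length x group matrix of inserted-residue counts).
#' @export
insertion_spectrum <- function(changes) {
  changes <- .parse_changes(changes)
  labs <- c(as.character(1:12), "13+")
  totals <- stats::setNames(integer(13), labs)
  by_group <- matrix(0L, 13, 4, dimnames = list(labs, AA_GROUPS))
  for (ch in changes) {
    if (ch$kind != "insertion") next
    lab <- if (ch$inserted_len > 12L) "13+" else as.character(ch$inserted_len)
    totals[lab] <- totals[lab] + 1L
    for (r in strsplit(ch$inserted_seq, "")[[1]]) {
      g <- aa_group(r)
      if (!is.na(g)) by_group[lab, g] <- by_group[lab, g] + 1L
    }
  }
  list(totals = totals, by_group = by_group)
}
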