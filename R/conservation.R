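#' Read an aligned FASTA file
#'
#' @param path aligned FASTA.
#' @return character matrix (rows = sequences, columns = alignment columns).
#' @export
readMSA <- function(path) {
  aln <- Biostrings::readAAStringSet(path, format = "fasta")
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L)
    stop("sequences are not aligned: unequal lengths")
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  rownames(m) <- names(aln)
  m
}

.as_msa_matrix <- function(msa) {
  if (is(msa, "AAMultipleAlignment") || is(msa, "AAStringSet"))
    msa <- as.matrix(msa)
  stopifnot(is.matrix(msa), is.character(msa))
  if (nrow(msa) < 2L) stop("alignment needs at least 2 sequences")
  toupper(msa)
}

#' Positional conservation index of an alignment
#'
#' Per column the raw index is the negated Shannon entropy of the amino-acid
#' frequencies, gaps excluded, so that zero (a fully conserved column) is the
#' maximum and more variable columns score lower. Columns with more than
#' \code{max_gap_frac} gaps are unscored. The raw indices are then z-scored
#' across scored columns, giving a centred profile (mean 0, sd 1) in which
#' positive values mark above-average conservation.
#'
#' @param msa character matrix, \code{AAMultipleAlignment} or
#'   \code{AAStringSet} (equal-length sequences).
#' @param ref_row alignment row used to map columns to residue numbers.
#' @param ref_start residue number of the reference sequence's first residue.
#' @param max_gap_frac columns with a higher gap fraction are unscored.
#' @param normalize z-score across scored columns (default TRUE).
#' @return a \linkS4class{ConservationProfile}.
#' @export
conservationIndex <- function(msa, ref_row = 1L, ref_start = 1L,
                              max_gap_frac = 0.5, normalize = TRUE) {
  m <- .as_msa_matrix(msa)
  gap <- m %in% c("-", ".", " ")
  dim(gap) <- dim(m)
  if (all(gap)) stop("all-gap alignment")
  L <- ncol(m)
  raw <- rep(NA_real_, L)
  for (j in seq_len(L)) {
    aa <- m[!gap[, j], j]
    if (length(aa) < (1 - max_gap_frac) * nrow(m)) next
    f <- table(aa) / length(aa)
    raw[j] <- sum(f * log(f))          # negated entropy: 0 = fully conserved
  }
  if (all(is.na(raw))) stop("no scorable columns")
  if (normalize) {
    v <- raw[!is.na(raw)]
    if (stats::sd(v) < 1e-12)
      stop("constant profile: all scored columns have identical composition")
    raw <- (raw - mean(v)) / stats::sd(v)
  }
  refgap <- gap[ref_row, ]
  resno <- rep(NA_integer_, L)
  resno[!refgap] <- seq.int(ref_start, length.out = sum(!refgap))
  new("ConservationProfile", values = raw, refResno = resno,
      refRow = as.integer(ref_row), normalized = normalize)
}

# per-residue conservation values for a set of reference residue numbers
.profile_at <- function(p, resnos) {
  p@values[match(resnos, p@refResno)]
}

#' Bin a conservation profile onto motif elements
#'
#' Each element's per-residue conservation values are treated as a
#' piecewise-constant function on [0, L); the value of bin i (of B) is the
#' function evaluated at the bin centre (i + 0.5) * L / B. The same rule
#' partitions a long element (L > B) and stretches a short one (L < B).
#'
#' @param p a \linkS4class{ConservationProfile}.
#' @param match an \linkS4class{RLMMatch} (element residue numbers must map
#'   into the profile's reference residues).
#' @param bins named integer vector of bin counts, e.g.
#'   \code{c(I = 5, II = 9, III = 5, IV = 7, V = 4)}; elements absent from
#'   the match are skipped.
#' @return a \linkS4class{BinnedProfile} (SE all zero, n = 1).
#' @export
binProfile <- function(p, match, bins) {
  stopifnot(is(p, "ConservationProfile"), is(match, "RLMMatch"))
  if (is.null(names(bins))) stop("bins must be a named vector")
  means <- list(); se <- list(); bc <- integer()
  for (e in names(bins)) {
    resn <- match@elements[[e]]
    if (e %in% c("catalytic_loop")) resn <- match@catalyticLoop
    if (e %in% c("crossover_loop")) resn <- match@crossoverLoop
    if (length(resn) == 0L) {
      if (e == "IV") next                      # loop-IV matches have no IV
      stop("element ", e, " has no residues")
    }
    v <- .profile_at(p, resn)
    means[[e]] <- .bin_values(v, as.integer(bins[[e]]))
    se[[e]] <- rep(0, bins[[e]])
    bc[e] <- as.integer(bins[[e]])
  }
  new("BinnedProfile", binCounts = bc, means = means, se = se, n = 1L)
}

# piecewise-constant bin evaluation: value at (i + 0.5) * L / B under floor
.bin_values <- function(v, B) {
  L <- length(v)
  if (L == 0L) stop("cannot bin an empty element")
  centers <- (seq_len(B) - 0.5) * L / B
  v[pmin(L, floor(centers) + 1L)]
}

#' Aggregate binned profiles across representatives
#'
#' @param profiles list of \linkS4class{BinnedProfile} with identical bin
#'   layouts.
#' @return a \linkS4class{BinnedProfile} with per-bin mean and standard error
#'   of the mean (SE = 0 for a single profile, by convention).
#' @export
aggregateBins <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  lay <- profiles[[1]]@binCounts
  for (p in profiles)
    if (!identical(p@binCounts, lay))
      stop("mismatched bin layouts")
  means <- list(); se <- list()
  n <- length(profiles)
  for (e in names(lay)) {
    m <- do.call(rbind, lapply(profiles, function(p) p@means[[e]]))
    means[[e]] <- colMeans(m, na.rm = TRUE)
    se[[e]] <- if (n > 1L)
      apply(m, 2, function(x) stats::sd(x, na.rm = TRUE) /
              sqrt(sum(!is.na(x))))
    else rep(0, lay[[e]])
  }
  new("BinnedProfile", binCounts = lay, means = means, se = se,
      n = as.integer(n))
}

#' Compare conservation inside vs outside the motif
#'
#' Partitions scored alignment positions into motif-element residues
#' (elements I-V; the connecting loops count as outside) versus all other
#' residues, and compares the two value sets with a two-sample
#' Kolmogorov-Smirnov test (asymptotic two-sided p-value).
#'
#' Explicit value vectors can be supplied instead of a profile + match, which
#' is convenient for power studies.
#'
#' @param p a \linkS4class{ConservationProfile} (or NULL when \code{inside}
#'   and \code{outside} are given).
#' @param match an \linkS4class{RLMMatch}.
#' @param domain_residues optional integer vector restricting the "outside"
#'   set to a domain.
#' @param inside,outside explicit numeric value vectors (override p/match).
#' @return list with \code{mean_in}, \code{mean_out}, \code{D},
#'   \code{p.value}, \code{n_in}, \code{n_out}.
#' @export
insideOutsideTest <- function(p = NULL, match = NULL, domain_residues = NULL,
                              inside = NULL, outside = NULL) {
  if (is.null(inside) || is.null(outside)) {
    stopifnot(is(p, "ConservationProfile"), is(match, "RLMMatch"))
    el <- unlist(match@elements, use.names = FALSE)
    scored <- which(!is.na(p@values) & !is.na(p@refResno))
    resn <- p@refResno[scored]
    if (!is.null(domain_residues)) {
      keep <- resn %in% domain_residues
      scored <- scored[keep]; resn <- resn[keep]
    }
    inside <- p@values[scored[resn %in% el]]
    outside <- p@values[scored[!resn %in% el]]
  }
  if (length(inside) == 0L || length(outside) == 0L)
    stop("empty partition: both residue sets must be non-empty")
  ks <- suppressWarnings(stats::ks.test(inside, outside, exact = FALSE))
  list(mean_in = mean(inside), mean_out = mean(outside),
       D = unname(ks$statistic), p.value = ks$p.value,
       n_in = length(inside), n_out = length(outside))
}

#' Default per-element bin counts from a set of matches
#'
#' The bin count of each element is the rounded mean element length over the
#' supplied matches (the average length distribution of the elements).
#'
#' @param matches list of \linkS4class{RLMMatch}.
#' @return named integer vector over the elements present.
#' @export
defaultBinCounts <- function(matches) {
  els <- c("I", "II", "III", "IV", "V")
  out <- integer()
  for (e in els) {
    lens <- vapply(matches, function(m) length(m@elements[[e]]), numeric(1))
    lens <- lens[lens > 0]
    if (length(lens)) out[e] <- max(1L, as.integer(round(mean(lens))))
  }
  out
}
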