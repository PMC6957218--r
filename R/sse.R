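#' Assign secondary-structure elements from backbone dihedrals
#'
#' Residues are labelled helix or strand by their backbone (phi, psi)
#' dihedrals (helix: phi in [-100, -30], psi in [-80, -5]; strand: phi in
#' [-180, -45], psi in [45, 225] mod 360), single-residue interruptions are
#' bridged, and maximal runs are segmented. Helices shorter than 4 residues
#' and strands shorter than 3 are discarded. Each element carries a
#' least-squares axis through its CA atoms. Alternatively a pre-computed
#' per-residue SSE string may be supplied.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param sse optional character vector of per-residue labels ("H", "E" or
#'   "-"), one per polymer residue in chain order, overriding the dihedral
#'   assignment (hook for externally computed secondary structure).
#' @param min_helix,min_strand minimum segment lengths retained.
#' @return an \linkS4class{SSESet}; empty when no chain has at least 4
#'   polymer residues.
#' @export
assignSSE <- function(s, sse = NULL, min_helix = 4L, min_strand = 3L) {
  stopifnot(is(s, "ProteinStructure"))
  res <- .residue_table(s)
  elements <- list(); axes <- list(); residues <- list()
  offset <- 0L
  for (ch in unique(res$chain)) {
    rc <- res[res$chain == ch, , drop = FALSE]
    n <- nrow(rc)
    if (!is.null(sse)) {
      lab <- sse[offset + seq_len(n)]
      offset <- offset + n
    } else {
      if (n < 4L) next
      lab <- .dihedral_labels(s, ch, rc)
    }
    lab <- .bridge_gaps(lab)
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      v <- r$values[k]
      len <- r$lengths[k]
      if (v == "H" && len >= min_helix) kind <- "helix"
      else if (v == "E" && len >= min_strand) kind <- "strand"
      else next
      idx <- starts[k]:ends[k]
      ca <- .atom_xyz(s, ch, rc$resno[idx], "CA")
      if (anyNA(ca)) next
      ax <- .fit_axis(ca)
      elements[[length(elements) + 1L]] <- data.frame(
        kind = kind, chain = ch, start = rc$resno[idx[1]],
        end = rc$resno[idx[length(idx)]], nres = len,
        stringsAsFactors = FALSE)
      axes[[length(axes) + 1L]] <- c(ax$dir, ax$start, ax$end)
      residues[[length(residues) + 1L]] <- rc$resno[idx]
    }
  }
  if (length(elements) == 0L)
    return(new("SSESet",
               elements = data.frame(index = integer(), kind = character(),
                                     chain = character(), start = integer(),
                                     end = integer(), nres = integer()),
               axes = matrix(numeric(), 0, 9), residues = list(),
               structureId = s@id))
  el <- do.call(rbind, elements)
  el <- cbind(index = seq_len(nrow(el)), el)
  new("SSESet", elements = el, axes = do.call(rbind, axes),
      residues = residues, structureId = s@id)
}

.dihedral_labels <- function(s, ch, rc) {
  n <- nrow(rc)
  N <- .atom_xyz(s, ch, rc$resno, "N")
  CA <- .atom_xyz(s, ch, rc$resno, "CA")
  C <- .atom_xyz(s, ch, rc$resno, "C")
  # peptide-bond connectivity: a C(i-1)..N(i) distance beyond 2.5 A marks a
  # chain break, across which dihedrals are undefined
  linked <- function(i)
    !anyNA(C[i - 1L, ]) && !anyNA(N[i, ]) &&
      sqrt(sum((C[i - 1L, ] - N[i, ])^2)) < 2.5
  lab <- rep("-", n)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next
    if (anyNA(CA[i, ]) || anyNA(C[i, ]) || anyNA(N[i + 1L, ])) next
    if (!linked(i) || !linked(i + 1L)) next
    phi <- .dihedral(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    psi <- .dihedral(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
    if (phi >= -100 && phi <= -30 && psi >= -80 && psi <= -5) lab[i] <- "H"
    else if (phi >= -180 && phi <= -45 &&
             (psi >= 45 || psi <= 225 - 360)) lab[i] <- "E"
  }
  lab
}

# bridge single-residue interruptions inside an otherwise uniform run
.bridge_gaps <- function(lab) {
  n <- length(lab)
  if (n < 3L) return(lab)
  out <- lab
  for (i in 2:(n - 1L))
    if (lab[i] != lab[i - 1L] && lab[i - 1L] == lab[i + 1L] &&
        lab[i - 1L] != "-") out[i] <- lab[i - 1L]
  out
}

#' Build the pairwise SSE interaction matrix
#'
#' For every ordered SSE pair the relation is coded: strand pairs linked by at
#' least two backbone N..O hydrogen bonds (< \code{hbond_cutoff}) are
#' \code{P} (parallel, positive axis dot product) or \code{A} (antiparallel);
#' pairs involving a helix whose minimum heavy-atom distance is below
#' \code{contact_cutoff} are \code{C} when the crossing angle is within
#' \code{t_angle_min} of collinear and \code{T} otherwise. Helix-strand
#' contacts carry a side sign relative to the least-squares plane through all
#' strand CA atoms (orientation arbitrary but consistent within the
#' structure). When a strand lacks N/O atoms the hydrogen-bond test falls
#' back to a CA-CA ladder (two consecutive residue pairs at 4.0-6.0 A).
#'
#' @param sses an \linkS4class{SSESet}.
#' @param s the \linkS4class{ProteinStructure} the SSEs were assigned from.
#' @param hbond_cutoff donor-acceptor N..O distance, Angstrom.
#' @param contact_cutoff minimum heavy-atom packing distance, Angstrom.
#' @param t_angle_min crossing angles in [t_angle_min, 180 - t_angle_min]
#'   degrees are coded "T", the rest "C".
#' @return an \linkS4class{InteractionMatrix}.
#' @export
buildInteractionMatrix <- function(sses, s, hbond_cutoff = 3.5,
                                   contact_cutoff = 6.5, t_angle_min = 30) {
  stopifnot(is(sses, "SSESet"), is(s, "ProteinStructure"))
  n <- nrow(sses@elements)
  codes <- matrix("none", n, n)
  sides <- matrix(NA_real_, n, n)
  angles <- matrix(NA_real_, n, n)
  if (n < 2L) return(new("InteractionMatrix", codes = codes, sides = sides,
                         angles = angles, sse = sses))
  el <- sses@elements
  ax <- sses@axes[, 1:3, drop = FALSE]
  heavy <- lapply(seq_len(n), function(i)
    .heavy_xyz(s, el$chain[i], sses@residues[[i]]))
  plane <- NULL
  st <- which(el$kind == "strand")
  if (length(st) > 0L) {
    ca_all <- do.call(rbind, lapply(st, function(i)
      .atom_xyz(s, el$chain[i], sses@residues[[i]], "CA")))
    if (nrow(ca_all) >= 3L) plane <- .fit_plane(ca_all)
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ang <- .vec_angle(ax[i, ], ax[j, ])
    angles[i, j] <- angles[j, i] <- ang
    ki <- el$kind[i]; kj <- el$kind[j]
    if (ki == "strand" && kj == "strand") {
      if (.strands_bonded(s, el, sses@residues, i, j, hbond_cutoff)) {
        code <- if (sum(ax[i, ] * ax[j, ]) > 0) "P" else "A"
        codes[i, j] <- codes[j, i] <- code
      }
    } else {
      if (.min_dist(heavy[[i]], heavy[[j]]) < contact_cutoff) {
        code <- if (ang < t_angle_min || ang > 180 - t_angle_min) "C" else "T"
        codes[i, j] <- codes[j, i] <- code
        if (ki != kj && !is.null(plane)) {
          h <- if (ki == "helix") i else j
          ctr <- colMeans(.atom_xyz(s, el$chain[h], sses@residues[[h]], "CA"))
          sides[i, j] <- sides[j, i] <-
            sign(sum((ctr - plane$center) * plane$normal))
        }
      }
    }
  }
  new("InteractionMatrix", codes = codes, sides = sides, angles = angles,
      sse = sses)
}

.strands_bonded <- function(s, el, residues, i, j, hbond_cutoff) {
  Ni <- .atom_xyz(s, el$chain[i], residues[[i]], "N")
  Oi <- .atom_xyz(s, el$chain[i], residues[[i]], "O")
  Nj <- .atom_xyz(s, el$chain[j], residues[[j]], "N")
  Oj <- .atom_xyz(s, el$chain[j], residues[[j]], "O")
  if (!anyNA(Ni) && !anyNA(Oi) && !anyNA(Nj) && !anyNA(Oj)) {
    nb <- sum(.pairdist(Ni, Oj) < hbond_cutoff) +
          sum(.pairdist(Oi, Nj) < hbond_cutoff)
    return(nb >= 2L)
  }
  # CA-only fallback: an inter-strand ladder of consecutive CA pairs
  cai <- .atom_xyz(s, el$chain[i], residues[[i]], "CA")
  caj <- .atom_xyz(s, el$chain[j], residues[[j]], "CA")
  D <- .pairdist(cai, caj)
  ok <- D >= 4.0 & D <= 6.0
  ni <- nrow(ok); nj <- ncol(ok)
  for (a in seq_len(ni - 1L)) for (b in seq_len(nj)) {
    if (!ok[a, b]) next
    if ((b < nj && ok[a + 1L, b + 1L]) || (b > 1L && ok[a + 1L, b - 1L]))
      return(TRUE)
  }
  FALSE
}

.pairdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Export an interaction matrix as TSV
#'
#' Writes one row per SSE (index, kind, range) followed by one row per
#' non-trivial pair (i, j, code, side, angle), so matches can be audited and
#' synthetic matrices injected.
#'
#' @param im an \linkS4class{InteractionMatrix}.
#' @param path output TSV file.
#' @return \code{path}, invisibly.
#' @export
exportInteractionMatrix <- function(im, path) {
  el <- im@sse@elements
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SSE\tindex\tkind\tchain\tstart\tend", con)
  for (i in seq_len(nrow(el)))
    writeLines(sprintf("SSE\t%d\t%s\t%s\t%d\t%d", el$index[i], el$kind[i],
                       el$chain[i], el$start[i], el$end[i]), con)
  writeLines("# PAIR\ti\tj\tcode\tside\tangle", con)
  n <- nrow(im@codes)
  for (i in seq_len(max(0, n - 1L))) for (j in (i + 1L):n)
    if (im@codes[i, j] != "none")
      writeLines(sprintf("PAIR\t%d\t%d\t%s\t%s\t%.1f", i, j, im@codes[i, j],
                         ifelse(is.na(im@sides[i, j]), "NA",
                                sprintf("%+d", as.integer(im@sides[i, j]))),
                         im@angles[i, j]), con)
  invisible(path)
}
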