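# Generators for ideal Rossmann-like motif structures and decoys.
#
# Backbone segments are built from ideal internal coordinates (NeRF chaining
# of N/CA/C/O with standard bond lengths and angles), canonicalised, and
# placed rigidly: a parallel beta2-beta1-beta3 sheet at fixed inter-strand
# spacing with the inter-strand registry grid-searched so that genuine
# backbone N..O hydrogen bonds (< 3.5 A) form, and alpha-helices packed on
# prescribed faces of the sheet. Connecting loops are smooth interpolating
# backbone paths with alternating local chirality: they keep the chain
# contiguous but never satisfy helix or strand dihedral windows, so assigned
# secondary structure is exactly the designed one. Loop conformations are not
# physically realistic; only secondary structure assignment and distances
# need to be correct.

.BOND <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231)
.ANG <- list(n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7, ca_c_o = 120.8)

# build an n-residue backbone with constant (phi, psi); returns a list of
# n matrices (rows N, CA, C, O)
.build_segment <- function(n, phi, psi) {
  stopifnot(n >= 1)
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(.BOND$n_ca, 0, 0)
  th <- .ANG$n_ca_c * pi / 180
  C <- CA + .BOND$ca_c * c(cos(pi - th), sin(pi - th), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      Np <- N; CAp <- CA; Cp <- C
      N <- .place_atom(Np, CAp, Cp, .BOND$c_n, .ANG$ca_c_n, psi)
      CA <- .place_atom(CAp, Cp, N, .BOND$n_ca, .ANG$c_n_ca, 180)
      C <- .place_atom(Cp, N, CA, .BOND$ca_c, .ANG$n_ca_c, phi)
    }
    O <- .place_atom(N, CA, C, .BOND$c_o, .ANG$ca_c_o, psi + 180)
    res[[i]] <- rbind(N = N, CA = CA, C = C, O = O)
  }
  res
}

# canonicalise: CA axis -> +x, CA centroid -> origin, second CA principal
# direction (the pleat for strands) -> +z
.canonical_segment <- function(seg) {
  ca <- t(vapply(seg, function(m) m["CA", ], numeric(3)))
  ctr <- colMeans(ca)
  x <- sweep(ca, 2, ctr)
  sv <- svd(x, nu = 0, nv = min(3, nrow(ca)))
  d1 <- sv$v[, 1]
  if (sum(d1 * (ca[nrow(ca), ] - ca[1, ])) < 0) d1 <- -d1
  d3 <- if (ncol(sv$v) >= 2) sv$v[, 2] else c(0, 0, 1)
  d3 <- d3 - sum(d3 * d1) * d1
  if (.norm(d3) < 1e-8) d3 <- c(0, 0, 1) - d1[3] * d1
  d3 <- .unit(d3)
  d2 <- .cross(d3, d1)
  R <- rbind(d1, d2, d3)   # rows: new x, y, z in old frame
  lapply(seg, function(m) t(R %*% (t(m) - ctr)))
}

.transform_segment <- function(seg, R = diag(3), t = c(0, 0, 0)) {
  lapply(seg, function(m) {
    out <- t(R %*% t(m))
    sweep(out, 2, t, "+")
  })
}

.segment_ca <- function(seg) t(vapply(seg, function(m) m["CA", ], numeric(3)))

.segment_atoms <- function(seg) do.call(rbind, seg)

# count backbone N..O hydrogen bonds (< hb A) between two placed segments
.count_hbonds <- function(segA, segB, hb = 3.5) {
  NA_ <- t(vapply(segA, function(m) m["N", ], numeric(3)))
  OA <- t(vapply(segA, function(m) m["O", ], numeric(3)))
  NB <- t(vapply(segB, function(m) m["N", ], numeric(3)))
  OB <- t(vapply(segB, function(m) m["O", ], numeric(3)))
  d1 <- outer(rowSums(NA_^2), rowSums(OB^2), "+") - 2 * NA_ %*% t(OB)
  d2 <- outer(rowSums(OA^2), rowSums(NB^2), "+") - 2 * OA %*% t(NB)
  sum(sqrt(pmax(d1, 0)) < hb) + sum(sqrt(pmax(d2, 0)) < hb)
}

# grid-search the rigid offset of strand B (canonical frame) relative to
# strand A so that the pair hydrogen-bonds like neighbouring sheet strands:
# lateral spacing near `spacing` along +y, registry shift along x, small z
# slide. Returns the best translation vector.
.sheet_offset <- function(tmplA, tmplB, spacing = 4.8, flipB = FALSE) {
  B0 <- if (flipB) .transform_segment(tmplB, .rot_axis(c(0, 0, 1), 180)) else tmplB
  caA <- .segment_ca(tmplA)
  best <- NULL; best_score <- -Inf
  for (dy in seq(spacing - 0.7, spacing + 0.7, by = 0.1)) {
    for (dx in seq(-3.5, 3.5, by = 0.25)) {
      for (dz in seq(-1.2, 1.2, by = 0.3)) {
        t <- c(dx, dy, dz)
        B <- .transform_segment(B0, t = t)
        nhb <- .count_hbonds(tmplA, B)
        if (nhb < 2L) next
        md <- .min_dist(.segment_atoms(tmplA), .segment_atoms(B))
        if (md < 2.2) next                     # steric clash
        score <- min(nhb, 4L) * 10 - abs(dy - spacing)
        if (score > best_score) { best_score <- score; best <- t }
      }
    }
  }
  if (is.null(best))
    stop("sheet registry search failed: no hydrogen-bonded placement found")
  best
}

# loop CA positions along a cubic Bezier between segment ends
.loop_path <- function(a, da, b, db, n) {
  p1 <- a + 2.8 * da
  p2 <- b - 2.8 * db
  tt <- seq_len(n) / (n + 1)
  t(vapply(tt, function(u)
    (1 - u)^3 * a + 3 * (1 - u)^2 * u * p1 + 3 * (1 - u) * u^2 * p2 + u^3 * b,
    numeric(3)))
}

# backbone atoms for loop residues: CA atoms sit on the interpolating path;
# each residue's C is placed by an internal-coordinate step that pins the
# backbone phi to +70 degrees. Positive phi lies outside both the helix and
# the strand dihedral windows, so loop residues can never be absorbed into a
# secondary-structure element regardless of how the path bends.
.loop_atoms <- function(path, prevCA, prevC, nextCA) {
  n <- nrow(path)
  out <- vector("list", n)
  Clast <- prevC
  CAlast <- prevCA
  for (i in seq_len(n)) {
    p <- path[i, ]
    u <- .unit(CAlast - p)
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    w <- .unit(ref - sum(ref * u) * u)
    N <- p + .BOND$n_ca * (cos(25 * pi / 180) * u + sin(25 * pi / 180) * w)
    C <- .place_atom(Clast, N, p, .BOND$ca_c, .ANG$n_ca_c, 70)
    O <- .place_atom(N, p, C, .BOND$c_o, .ANG$ca_c_o, 130)
    out[[i]] <- rbind(N = N, CA = p, C = C, O = O)
    Clast <- C
    CAlast <- p
  }
  out
}

# assemble placed segments (list of list(kind, seg)) into one chain with
# interpolating loops; returns list(atoms data.frame, ranges data.frame)
.assemble_chain <- function(parts, loop_min = 2L) {
  blocks <- list(); kinds <- character(); labels <- character()
  for (i in seq_along(parts)) {
    if (i > 1L) {
      prevseg <- parts[[i - 1]]$seg
      nextseg <- parts[[i]]$seg
      caP <- .segment_ca(prevseg); caN <- .segment_ca(nextseg)
      a <- caP[nrow(caP), ]; b <- caN[1, ]
      da <- .unit(a - caP[nrow(caP) - 1, ])
      db <- .unit(caN[2, ] - b)
      nl <- max(loop_min, ceiling((.norm(b - a) - 3.5) / 3.4))
      path <- .loop_path(a, da, b, db, nl)
      prevC <- prevseg[[length(prevseg)]]["C", ]
      blocks <- c(blocks, list(.loop_atoms(path, a, prevC, b)))
      kinds <- c(kinds, "loop"); labels <- c(labels, "")
    }
    blocks <- c(blocks, list(parts[[i]]$seg))
    kinds <- c(kinds, parts[[i]]$kind)
    labels <- c(labels, parts[[i]]$label)
  }
  rows <- list(); ranges <- list(); resno <- 0L
  for (k in seq_along(blocks)) {
    start <- resno + 1L
    for (res in blocks[[k]]) {
      resno <- resno + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        chain = "A", resno = resno, ins = "", resname = "GLY",
        atom = rownames(res), element = substr(rownames(res), 1, 1),
        x = res[, 1], y = res[, 2], z = res[, 3], het = FALSE,
        stringsAsFactors = FALSE)
    }
    ranges[[k]] <- data.frame(kind = kinds[k], label = labels[k],
                              start = start, end = resno,
                              stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  list(atoms = atoms, ranges = do.call(rbind, ranges))
}

# core engine: lay out the motif per options and return structure + truth
.build_rlm <- function(id, strand_len = 6L, helix_len = 10L, spacing = 4.8,
                       helix_height = NULL, helix_angle_II = 0,
                       insertion = FALSE, ligand = FALSE,
                       variant = c("helix-IV", "strand-IV", "loop-IV"),
                       decoy = c("none", "antiparallel_V", "short_strand",
                                 "no_crossover", "same_face_helices"),
                       loop_min = 2L) {
  variant <- match.arg(variant)
  decoy <- match.arg(decoy)
  sl <- function(nm) if (decoy == "short_strand" && nm == "III") 2L else strand_len
  tS <- list(I = .canonical_segment(.build_segment(sl("I"), -120, 120)),
             III = .canonical_segment(.build_segment(sl("III"), -120, 120)),
             V = .canonical_segment(.build_segment(sl("V"), -120, 120)))
  tH <- .canonical_segment(.build_segment(helix_len, -57, -47))

  off <- .sheet_offset(tS$I, tS$III, spacing)
  segI <- tS$I
  segIII <- .transform_segment(tS$III, t = -off)
  if (decoy == "antiparallel_V") {
    offA <- .sheet_offset(tS$I, tS$V, spacing, flipB = TRUE)
    segV <- .transform_segment(
      .transform_segment(tS$V, .rot_axis(c(0, 0, 1), 180)), t = offA)
  } else if (decoy == "no_crossover") {
    segV <- .transform_segment(tS$V, t = -2 * off)
  } else {
    segV <- .transform_segment(tS$V, t = off)
  }

  sheet_atoms <- rbind(.segment_atoms(segI), .segment_atoms(segIII),
                       .segment_atoms(segV))
  cx <- mean(.segment_ca(segI)[, 1])

  # pack a helix over a face: pick |z| so the closest heavy-atom distance to
  # the sheet is ~4.5 A (well inside the 6.5 A packing cutoff)
  place_helix <- function(y, zsign, angle = 0) {
    R <- .rot_axis(c(0, 0, 1), 180 + angle)    # run antiparallel to strands
    h0 <- .transform_segment(tH, R)
    pick <- NULL
    for (h in seq(6, 14, by = 0.1)) {
      hs <- .transform_segment(h0, t = c(cx, y, zsign * h))
      md <- .min_dist(.segment_atoms(hs), sheet_atoms)
      if (md >= 4.2) { pick <- hs; break }
    }
    if (is.null(pick)) stop("helix placement failed")
    pick
  }

  zII <- +1
  zIV <- if (decoy == "same_face_helices") +1 else -1
  segII <- place_helix(-spacing / 2, zII, helix_angle_II)
  segIV <- if (variant == "helix-IV") place_helix(+spacing / 2, zIV) else NULL
  if (variant == "strand-IV") {
    # crossover carried by a short strand on the far edge beside element V
    tX <- .canonical_segment(.build_segment(5L, -120, 120))
    offX <- .sheet_offset(tS$V, tX, spacing)
    segIV <- .transform_segment(tX, t = off + offX)
  }

  parts <- list(list(kind = "strand", label = "I", seg = segI),
                list(kind = "helix", label = "II", seg = segII),
                list(kind = "strand", label = "III", seg = segIII))
  if (insertion) {
    tBi <- .canonical_segment(.build_segment(strand_len, -120, 120))
    offB <- .sheet_offset(tS$III, tBi, spacing)
    segBi <- .transform_segment(tBi, t = -off - offB)
    segAi <- place_helix(-1.5 * spacing, +1)
    parts <- c(parts, list(list(kind = "strand", label = "ins_b", seg = segBi),
                           list(kind = "helix", label = "ins_a", seg = segAi)))
  }
  if (!is.null(segIV))
    parts <- c(parts, list(list(kind = if (variant == "strand-IV") "strand"
                                       else "helix", label = "IV", seg = segIV)))
  parts <- c(parts, list(list(kind = "strand", label = "V", seg = segV)))

  asm <- .assemble_chain(parts, loop_min = loop_min)
  atoms <- asm$atoms
  ranges <- asm$ranges

  lig_center <- NULL
  if (ligand) {
    # place a small compound in the beta1/beta3 crevice at the C-terminal
    # edge of the sheet, above the plane
    caI <- .segment_ca(segI); caV <- .segment_ca(segV)
    lig_center <- 0.5 * (caI[nrow(caI), ] + caV[nrow(caV), ]) +
      c(-2.5, -2.0, 2.0)
    lig <- rbind(lig_center,
                 lig_center + c(0.9, 0.9, 0.3),
                 lig_center + c(-0.6, -0.9, 0.8),
                 lig_center + c(0.2, 0.4, -1.0))
    atoms <- rbind(atoms, data.frame(
      chain = "A", resno = max(atoms$resno) + 10L, ins = "",
      resname = "LIG", atom = paste0("C", 1:4), element = "C",
      x = lig[, 1], y = lig[, 2], z = lig[, 3], het = TRUE,
      stringsAsFactors = FALSE))
  }

  s <- new("ProteinStructure", id = id, atoms = atoms)
  truth <- NULL
  if (decoy == "none") {
    el <- function(lbl) {
      r <- ranges[ranges$label == lbl, ]
      if (nrow(r)) seq.int(r$start, r$end) else integer()
    }
    seg_rows <- which(ranges$label != "" | ranges$kind != "loop")
    ivpos <- which(ranges$label == "IV")
    prev_end <- if (length(ivpos)) ranges$end[max(which(seq_len(nrow(ranges)) <
                  ivpos & ranges$kind != "loop"))] else NA
    cross <- if (length(ivpos)) seq.int(prev_end + 1L, ranges$start[ivpos] - 1L)
             else {
               vpos <- which(ranges$label == "V")
               p <- ranges$end[max(which(seq_len(nrow(ranges)) < vpos &
                                         ranges$kind != "loop"))]
               seq.int(p + 1L, ranges$start[vpos] - 1L)
             }
    cat_loop <- seq.int(max(el("I")) + 1L, min(el("II")) - 1L)
    truth <- new("RLMMatch", structureId = id, domainId = "",
                 variant = variant,
                 elements = list(I = el("I"), II = el("II"), III = el("III"),
                                 IV = el("IV"), V = el("V")),
                 catalyticLoop = as.integer(cat_loop),
                 crossoverLoop = as.integer(cross),
                 chain = "A",
                 sseIndices = stats::setNames(integer(0), character(0)),
                 flags = character())
  }
  list(structure = s, match = truth, ranges = ranges,
       domain = sprintf("A:%d-%d", min(atoms$resno[!atoms$het]),
                        max(atoms$resno[!atoms$het])),
       ligandCenter = lig_center)
}

#' Generate an ideal minimal Rossmann-like motif structure
#'
#' Builds a synthetic three-layer alpha/beta/alpha sandwich from ideal
#' backbone dihedrals: a parallel beta2-beta1-beta3 sheet (beta1 central) with
#' real backbone hydrogen bonds at the requested inter-strand spacing, an
#' alpha-helix packed on each face (element II above, element IV below, i.e.
#' on opposite faces as the crossover demands), and smooth connecting loops.
#' The ground-truth motif annotation is returned alongside the structure so
#' downstream assertions are self-contained.
#'
#' @param seed integer; kept for interface uniformity (construction is fully
#'   deterministic, so the same seed and parameters give identical output).
#' @param strand_len residues per beta-strand (>= 3).
#' @param helix_len residues per alpha-helix (>= 4).
#' @param spacing inter-strand spacing in Angstrom.
#' @param helix_angle_II crossing angle (degrees) added to element II's
#'   packing orientation; 0 gives a near-collinear "C" contact, ~60 gives an
#'   angled "T" contact.
#' @param insertion add a beta-alpha insertion between elements III and IV
#'   (the classic Rossmann mimic); the insertion is excluded from the motif.
#' @param variant crossover element type: "helix-IV", "strand-IV" or
#'   "loop-IV" (element IV absent, crossover carried by the loop).
#' @param ligand place a small hetero compound in the beta1/beta3 crevice.
#' @return list with \code{structure} (\linkS4class{ProteinStructure}),
#'   \code{match} (ground-truth \linkS4class{RLMMatch}), \code{ranges}
#'   (segment layout), \code{domain} (range string covering the chain) and
#'   \code{ligandCenter} (or NULL).
#' @export
makeIdealRLM <- function(seed = 1L, strand_len = 6L, helix_len = 10L,
                         spacing = 4.8, helix_angle_II = 0,
                         insertion = FALSE,
                         variant = c("helix-IV", "strand-IV", "loop-IV"),
                         ligand = FALSE) {
  variant <- match.arg(variant)
  .build_rlm(id = sprintf("ideal_rlm_s%d", as.integer(seed)),
             strand_len = strand_len, helix_len = helix_len,
             spacing = spacing, helix_angle_II = helix_angle_II,
             insertion = insertion, variant = variant, ligand = ligand)
}

#' Generate a decoy structure violating exactly one motif clause
#'
#' Each decoy family perturbs a single clause of the motif definition so test
#' failures localise: \code{antiparallel_V} flips the last strand (beta3
#' hydrogen-bonds beta1 antiparallel), \code{short_strand} shortens beta2 to
#' two residues, \code{no_crossover} places beta3 on the far side of beta2
#' (sheet order beta1-beta2-beta3, no bond to beta1), and
#' \code{same_face_helices} puts both helices on the same sheet face.
#'
#' @param kind decoy family.
#' @param seed integer, kept for interface uniformity.
#' @return list with \code{structure} and NULL \code{match}.
#' @export
makeDecoy <- function(kind = c("antiparallel_V", "short_strand",
                               "no_crossover", "same_face_helices"),
                      seed = 1L) {
  kind <- match.arg(kind)
  .build_rlm(id = sprintf("decoy_%s_s%d", kind, as.integer(seed)),
             decoy = kind)
}
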