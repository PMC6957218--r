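#' Match the minimal Rossmann-like motif against an interaction matrix
#'
#' Enumerates SSE tuples (I, II, III, IV, V) satisfying the motif definition:
#' strand/helix/strand/\{helix|strand|absent\}/strand in strict sequence
#' order; element II is the SSE immediately after I (the first wind carries
#' no insertions) and III immediately follows II; arbitrary intervening SSEs
#' (insertions) are allowed between III and IV and between IV and V; elements
#' III and V are each parallel hydrogen-bonded to the central strand I;
#' element II packs (C or T) against I on side s of the sheet; a helical
#' element IV must pack against I or V on side -s (the crossover places it on
#' the opposite face); a strand IV carries no side constraint; the loop-IV
#' variant is accepted when no SSE lies between III and V and the crossover
#' loop has at least 2 residues. All three strands must be at least 3
#' residues. Matches reaching the same element V through different IV
#' candidates are deduplicated preferring helix-IV > strand-IV > loop-IV
#' (ties resolved to the IV nearest V).
#'
#' Side signs are evaluated against the least-squares plane through the CA
#' atoms of the candidate's own three strands, so the test is local to each
#' candidate sheet.
#'
#' @param im an \linkS4class{InteractionMatrix}.
#' @param s the \linkS4class{ProteinStructure} (needed for side-plane fits
#'   and loop residue lookup).
#' @return list of \linkS4class{RLMMatch} objects, ordered by element-I then
#'   element-V start residue; empty list when nothing matches.
#' @export
matchRLM <- function(im, s) {
  stopifnot(is(im, "InteractionMatrix"), is(s, "ProteinStructure"))
  sses <- im@sse
  el <- sses@elements
  n <- nrow(el)
  if (n < 3L) return(list())
  codes <- im@codes
  found <- list()
  for (i in seq_len(n)) {
    if (el$kind[i] != "strand" || el$nres[i] < 3L) next
    ii <- i + 1L
    if (ii > n || el$kind[ii] != "helix") next
    iii <- ii + 1L
    if (iii > n || el$kind[iii] != "strand" || el$nres[iii] < 3L) next
    if (el$chain[i] != el$chain[ii] || el$chain[ii] != el$chain[iii]) next
    if (codes[i, iii] != "P") next
    if (!codes[i, ii] %in% c("C", "T")) next
    for (v in seq_len(n)) {
      if (v <= iii || el$kind[v] != "strand" || el$nres[v] < 3L) next
      if (el$chain[v] != el$chain[i]) next
      if (codes[i, v] != "P") next
      sideof <- .side_fn(s, sses, c(i, iii, v))
      s_II <- sideof(ii)
      if (is.na(s_II) || s_II == 0) next
      cand <- list()
      between <- setdiff(seq.int(iii + 1L, v - 1L), integer(0))
      between <- between[between > iii & between < v]
      for (m in between) {
        if (el$kind[m] == "helix") {
          ok <- (codes[m, i] %in% c("C", "T") || codes[m, v] %in% c("C", "T"))
          if (ok && isTRUE(sideof(m) == -s_II))
            cand[[length(cand) + 1L]] <- list(idx = m, variant = "helix-IV")
        } else if (el$kind[m] == "strand") {
          cand[[length(cand) + 1L]] <- list(idx = m, variant = "strand-IV")
        }
      }
      if (length(cand) == 0L && length(between) == 0L) {
        gap <- .loop_residues(s, el$chain[i], el$end[iii], el$start[v])
        if (length(gap) >= 2L)
          cand[[length(cand) + 1L]] <- list(idx = NA_integer_,
                                            variant = "loop-IV")
      }
      if (length(cand) == 0L) next
      pri <- c("helix-IV" = 1L, "strand-IV" = 2L, "loop-IV" = 3L)
      vr <- vapply(cand, `[[`, character(1), "variant")
      iv <- vapply(cand, `[[`, integer(1), "idx")
      ord <- order(pri[vr], -ifelse(is.na(iv), -Inf, iv))
      pick <- cand[[ord[1]]]
      found[[length(found) + 1L]] <-
        .make_match(s, sses, i, ii, iii, pick$idx, v, pick$variant)
    }
  }
  if (length(found) == 0L) return(list())
  o <- order(vapply(found, function(m) min(m@elements$I), numeric(1)),
             vapply(found, function(m) min(m@elements$V), numeric(1)))
  found[o]
}

# side-sign function against the plane of the candidate's own strands
.side_fn <- function(s, sses, strand_idx) {
  ca <- do.call(rbind, lapply(strand_idx, function(k)
    .atom_xyz(s, sses@elements$chain[k], sses@residues[[k]], "CA")))
  pl <- .fit_plane(ca)
  function(k) {
    ctr <- colMeans(.atom_xyz(s, sses@elements$chain[k],
                              sses@residues[[k]], "CA"))
    sign(sum((ctr - pl$center) * pl$normal))
  }
}

# polymer residue numbers strictly between two residue numbers on a chain
.loop_residues <- function(s, chain, after, before) {
  res <- .residue_table(s)
  r <- res$resno[res$chain == chain]
  as.integer(r[r > after & r < before])
}

.make_match <- function(s, sses, i, ii, iii, iv, v, variant) {
  el <- sses@elements
  ch <- el$chain[i]
  elem <- list(I = as.integer(sses@residues[[i]]),
               II = as.integer(sses@residues[[ii]]),
               III = as.integer(sses@residues[[iii]]),
               IV = if (is.na(iv)) integer() else
                 as.integer(sses@residues[[iv]]),
               V = as.integer(sses@residues[[v]]))
  cat_loop <- .loop_residues(s, ch, el$end[i], el$start[ii])
  if (is.na(iv)) {
    prev <- iii
    cross <- .loop_residues(s, ch, el$end[prev], el$start[v])
  } else {
    prev <- iv - 1L   # SSE immediately preceding IV (III or last insertion)
    cross <- .loop_residues(s, ch, el$end[prev], el$start[iv])
  }
  idx <- c(I = i, II = ii, III = iii, IV = if (is.na(iv)) NA_integer_ else iv,
           V = v)
  new("RLMMatch", structureId = sses@structureId, domainId = "",
      variant = variant, elements = elem,
      catalyticLoop = cat_loop, crossoverLoop = cross, chain = ch,
      sseIndices = idx[!is.na(idx)], flags = character())
}

#' Anchor motif matches to domains
#'
#' A match is kept only when every residue of its elements lies inside
#' exactly one domain's range; kept matches carry that domain id, so no match
#' spans two domains. When several matches survive in one domain all are
#' retained; the one with the smallest element-I start residue is flagged
#' \code{"canonical"}, the others \code{"secondary"}.
#'
#' @param matches list of \linkS4class{RLMMatch}.
#' @param domains data.frame with columns \code{id} and \code{range} (ECOD
#'   dialect range strings), or a named list of \linkS4class{DomainRange}.
#' @return list of retained \linkS4class{RLMMatch} with \code{domainId} set.
#' @export
assignToDomain <- function(matches, domains) {
  if (is.data.frame(domains)) {
    ids <- domains$id
    drs <- lapply(domains$range, parseDomainRange)
  } else {
    ids <- names(domains)
    drs <- domains
  }
  segs <- do.call(rbind, lapply(seq_along(drs), function(k)
    cbind(drs[[k]]@segments, id = ids[k])))
  # warn on overlapping domains within a chain
  for (ch in unique(segs$chain)) {
    sc <- segs[segs$chain == ch, , drop = FALSE]
    sc <- sc[order(sc$start), , drop = FALSE]
    if (nrow(sc) > 1L && any(sc$start[-1] <= sc$end[-nrow(sc)]))
      warning("overlapping domain ranges on chain ", ch)
  }
  in_dom <- function(m, dr) {
    resn <- unlist(m@elements, use.names = FALSE)
    sg <- dr@segments
    all(vapply(resn, function(r)
      any(sg$chain == m@chain & sg$start <= r & sg$end >= r), logical(1)))
  }
  kept <- list()
  for (m in matches) {
    hit <- which(vapply(drs, in_dom, logical(1), m = m))
    if (length(hit) == 1L) {
      m@domainId <- ids[hit]
      kept[[length(kept) + 1L]] <- m
    }
  }
  if (length(kept) > 1L) {
    dom <- vapply(kept, function(m) paste(m@structureId, m@domainId),
                  character(1))
    for (d in unique(dom)) {
      sel <- which(dom == d)
      if (length(sel) > 1L) {
        starts <- vapply(kept[sel], function(m) min(m@elements$I), numeric(1))
        for (k in seq_along(sel))
          kept[[sel[k]]]@flags <- if (k == which.min(starts)) "canonical"
                                  else "secondary"
      }
    }
  }
  kept
}

#' Tabulate motif matches
#'
#' @param matches list of \linkS4class{RLMMatch}.
#' @return data.frame with one row per match: structure, domain, variant,
#'   chain and residue ranges of elements I-V and both loops.
#' @export
matchTable <- function(matches) {
  rng <- function(r) if (length(r)) sprintf("%d-%d", min(r), max(r)) else ""
  if (length(matches) == 0L)
    return(data.frame(structure = character(), domain = character(),
                      variant = character(), chain = character(),
                      I = character(), II = character(), III = character(),
                      IV = character(), V = character(),
                      catalytic_loop = character(),
                      crossover_loop = character(), flags = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(matches, function(m) data.frame(
    structure = m@structureId, domain = m@domainId, variant = m@variant,
    chain = m@chain,
    I = rng(m@elements$I), II = rng(m@elements$II), III = rng(m@elements$III),
    IV = rng(m@elements$IV), V = rng(m@elements$V),
    catalytic_loop = rng(m@catalyticLoop),
    crossover_loop = rng(m@crossoverLoop),
    flags = paste(m@flags, collapse = ";"),
    stringsAsFactors = FALSE)))
}
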