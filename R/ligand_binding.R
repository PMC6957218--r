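# Ligand contacts, compound taxonomy, biological-significance flags and
# binding-mode pooling via element-anchored Kabsch superposition.

# common crystallization additives excluded from contact reports by default
.default_blocklist <- c("GOL", "EDO", "PEG", "PG4", "SO4", "PO4", "ACT",
                        "DMS", "MPD", "TRS", "FMT", "BME", "EPE", "MES")

# the CTP-derivative compounds manually assigned to the nucleotide superclass
.ctp_override <- c("C00063", "C00705", "C05673", "C05674", "C05822")
.nucleotide_superclass <- "Nucleosides, nucleotides, and analogues"

#' Ligand contacts within a distance cutoff of a domain
#'
#' One contact is reported per hetero residue having any heavy atom within
#' \code{cutoff} Angstrom of any heavy atom of the domain's polymer residues.
#' When a motif match is supplied, every motif region (elements I-V, the
#' catalytic and crossover loops) containing a residue within the cutoff of
#' the ligand is attributed; contacting domain residues belonging to no
#' region are reported as \code{outside-RLM}.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param domain_residues data.frame (\code{chain}, \code{resno}) as from
#'   \code{\link{residuesInRange}}, or NULL for all polymer residues.
#' @param match optional \linkS4class{RLMMatch} for element attribution.
#' @param cutoff contact distance in Angstrom (default 4.0).
#' @param blocklist hetero residue names to ignore (waters are never
#'   considered; crystallization additives by default).
#' @return data.frame: structure, ligand, chain, resno, min_dist, elements
#'   (comma-separated regions); zero rows when nothing is in contact.
#' @export
findContacts <- function(s, domain_residues = NULL, match = NULL,
                         cutoff = 4.0, blocklist = .default_blocklist) {
  stopifnot(is(s, "ProteinStructure"), cutoff > 0)
  a <- s@atoms
  if (is.null(domain_residues))
    domain_residues <- .residue_table(s)[, c("chain", "resno")]
  pol <- a[!a$het & a$element != "H" &
           paste(a$chain, a$resno) %in%
             paste(domain_residues$chain, domain_residues$resno), ,
           drop = FALSE]
  het <- a[a$het & a$element != "H" &
           !a$resname %in% c(blocklist, "HOH", "WAT", "DOD"), , drop = FALSE]
  if (nrow(het) == 0L || nrow(pol) == 0L)
    return(data.frame(structure = character(), ligand = character(),
                      chain = character(), resno = integer(),
                      min_dist = numeric(), elements = character()))
  P <- as.matrix(pol[, c("x", "y", "z")])
  out <- list()
  for (key in unique(paste(het$chain, het$resno, het$resname))) {
    sel <- paste(het$chain, het$resno, het$resname) == key
    H <- as.matrix(het[sel, c("x", "y", "z"), drop = FALSE])
    D <- .pairdist(H, P)
    md <- min(D)
    if (md > cutoff) next
    lig <- het[sel, ][1, ]
    elems <- character()
    if (!is.null(match)) {
      contact_res <- unique(paste(pol$chain, pol$resno)[
        apply(D <= cutoff, 2, any)])
      regions <- c(match@elements,
                   list(catalytic_loop = match@catalyticLoop,
                        crossover_loop = match@crossoverLoop))
      attributed <- rep(FALSE, length(contact_res))
      for (e in names(regions)) {
        r <- regions[[e]]
        if (length(r) == 0L) next
        hit <- contact_res %in% paste(match@chain, r)
        if (any(hit)) {
          elems <- c(elems, e)
          attributed <- attributed | hit
        }
      }
      if (any(!attributed)) elems <- c(elems, "outside-RLM")
    }
    out[[length(out) + 1L]] <- data.frame(
      structure = s@id, ligand = lig$resname, chain = lig$chain,
      resno = lig$resno, min_dist = md,
      elements = paste(elems, collapse = ","), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(structure = character(), ligand = character(),
                      chain = character(), resno = integer(),
                      min_dist = numeric(), elements = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify compounds into taxonomy superclasses
#'
#' Table lookup against a chemical-taxonomy table (kingdom / superclass /
#' class), with two totality rules: compounds on the CTP-derivative override
#' list are assigned the nucleotide superclass regardless of the table, and
#' any compound found nowhere falls back to the ad-hoc "Generic compounds"
#' superclass. Override beats table beats fallback.
#'
#' @param ids character vector of compound ids.
#' @param taxonomy data.frame with columns \code{compound}, \code{kingdom},
#'   \code{superclass}, \code{class}.
#' @return data.frame: compound, kingdom, superclass, class, source
#'   (taxonomy-table / generic-fallback / manual-override).
#' @export
classifyCompound <- function(ids, taxonomy) {
  hit <- match(ids, taxonomy$compound)
  out <- data.frame(
    compound = ids,
    kingdom = ifelse(is.na(hit), NA_character_, taxonomy$kingdom[hit]),
    superclass = ifelse(is.na(hit), "Generic compounds",
                        taxonomy$superclass[hit]),
    class = ifelse(is.na(hit), NA_character_, taxonomy$class[hit]),
    source = ifelse(is.na(hit), "generic-fallback", "taxonomy-table"),
    stringsAsFactors = FALSE)
  ov <- out$compound %in% .ctp_override
  out$superclass[ov] <- .nucleotide_superclass
  out$source[ov] <- "manual-override"
  out
}

#' Flag the biological significance of a ligand contact
#'
#' A bound compound is biologically significant when it is a substrate or
#' product of any EC reaction assigned to the structure, or one of the
#' structure's annotated cofactors; otherwise (including unmapped ligands) it
#' is of uncertain significance.
#'
#' @param compound compound id (NA for an unmapped ligand).
#' @param ecs character vector of EC numbers assigned to the structure.
#' @param substrates,products data.frames with columns \code{ec},
#'   \code{compound}.
#' @param cofactors character vector of cofactor compound ids for the
#'   structure (or data.frame \code{ec}, \code{compound}).
#' @return \code{"significant"} or \code{"uncertain"}.
#' @export
flagSignificance <- function(compound, ecs, substrates, products,
                             cofactors = character()) {
  if (is.na(compound) || length(ecs) == 0L) return("uncertain")
  pool <- c(substrates$compound[substrates$ec %in% ecs],
            products$compound[products$ec %in% ecs])
  if (is.data.frame(cofactors))
    pool <- c(pool, cofactors$compound[cofactors$ec %in% ecs])
  else pool <- c(pool, cofactors)
  if (compound %in% pool) "significant" else "uncertain"
}

# CA coordinates of a match's element residues, trimmed per element:
# each element pair is trimmed symmetrically about its centre to the
# shorter length before building the one-to-one correspondence
.match_correspondence <- function(sm, mm, sr, mr) {
  els <- c("I", "II", "III", "V")
  if (sm@variant == "helix-IV" && mm@variant == "helix-IV")
    els <- c("I", "II", "III", "IV", "V")
  P <- NULL; Q <- NULL
  for (e in els) {
    r1 <- mm@elements[[e]]; r2 <- sm@elements[[e]]
    l <- min(length(r1), length(r2))
    if (l == 0L) next
    trim <- function(r) {
      off <- (length(r) - l) %/% 2
      r[off + seq_len(l)]
    }
    P <- rbind(P, .atom_xyz(mr, mm@chain, trim(r1), "CA"))
    Q <- rbind(Q, .atom_xyz(sr, sm@chain, trim(r2), "CA"))
  }
  ok <- !apply(is.na(P), 1, any) & !apply(is.na(Q), 1, any)
  list(P = P[ok, , drop = FALSE], Q = Q[ok, , drop = FALSE])
}

#' Superpose one motif onto another (element-anchored Kabsch)
#'
#' Builds a residue correspondence element by element (I, II, III, V, and IV
#' when both matches have a helical IV), trimming each element pair
#' symmetrically about its centre to the shorter length, then finds the
#' optimal rigid transform by the Kabsch algorithm on corresponding CA atoms.
#' Applying the returned rotation and translation to mobile coordinates
#' (rows) maps them into the reference frame.
#'
#' @param mobile,reference lists with components \code{structure}
#'   (\linkS4class{ProteinStructure}) and \code{match}
#'   (\linkS4class{RLMMatch}).
#' @return a \linkS4class{Superposition}.
#' @export
superposeRLM <- function(mobile, reference) {
  cor <- .match_correspondence(reference$match, mobile$match,
                               reference$structure, mobile$structure)
  if (nrow(cor$P) < 9L)
    stop("under-determined superposition: correspondence has ",
         nrow(cor$P), " atoms (< 9)")
  k <- .kabsch(cor$P, cor$Q)
  new("Superposition", rotation = k$rotation, translation = k$translation,
      rmsd = k$rmsd, n = nrow(cor$P))
}

#' Apply a superposition to coordinates
#'
#' @param sp a \linkS4class{Superposition}.
#' @param xyz n x 3 coordinate matrix (rows are points).
#' @return transformed n x 3 matrix.
#' @export
applySuperposition <- function(sp, xyz) {
  stopifnot(is(sp, "Superposition"))
  sweep(xyz %*% t(sp@rotation), 2, sp@translation, "+")
}

#' Pool ligands of a homolog group into one reference frame
#'
#' Superposes every group member's motif onto the reference member's and
#' transforms the members' ligand heavy atoms into the reference frame,
#' annotated with their compound superclass when a taxonomy is supplied.
#' Members whose superposition fails are skipped with a warning. A per-member
#' motif-only RMSD table is attached as quality control.
#'
#' @param group list of members, each a list with \code{structure},
#'   \code{match}, and optionally \code{ligands} (data.frame \code{resname},
#'   \code{compound}) mapping hetero residues to compound ids.
#' @param reference index of the reference member.
#' @param taxonomy optional compound taxonomy table for superclass labels.
#' @return list with \code{atoms} (data.frame: structure, resname, atom,
#'   x, y, z, superclass) and \code{rmsd} (per-member table).
#' @export
poolLigands <- function(group, reference = 1L, taxonomy = NULL) {
  stopifnot(length(group) >= 1L)
  ref <- group[[reference]]
  rows <- list(); rmsds <- list()
  for (k in seq_along(group)) {
    g <- group[[k]]
    sp <- if (k == reference)
      new("Superposition", rotation = diag(3), translation = c(0, 0, 0),
          rmsd = 0, n = 0L)
    else tryCatch(superposeRLM(g, ref), error = function(e) {
      warning("skipping member ", k, " (", g$structure@id, "): ",
              conditionMessage(e))
      NULL
    })
    if (is.null(sp)) next
    rmsds[[length(rmsds) + 1L]] <- data.frame(
      structure = g$structure@id, rmsd = sp@rmsd, n = sp@n,
      stringsAsFactors = FALSE)
    a <- g$structure@atoms
    lig <- a[a$het & a$element != "H" &
             !a$resname %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
    if (nrow(lig) == 0L) next
    xyz <- applySuperposition(sp, as.matrix(lig[, c("x", "y", "z")]))
    sc <- rep(NA_character_, nrow(lig))
    if (!is.null(g$ligands)) {
      comp <- g$ligands$compound[match(lig$resname, g$ligands$resname)]
      if (!is.null(taxonomy))
        sc <- classifyCompound(comp, taxonomy)$superclass
      else sc <- comp
    }
    rows[[length(rows) + 1L]] <- data.frame(
      structure = g$structure@id, resname = lig$resname, atom = lig$atom,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], superclass = sc,
      stringsAsFactors = FALSE)
  }
  atoms <- if (length(rows)) do.call(rbind, rows) else
    data.frame(structure = character(), resname = character(),
               atom = character(), x = numeric(), y = numeric(),
               z = numeric(), superclass = character())
  rownames(atoms) <- NULL
  list(atoms = atoms, rmsd = do.call(rbind, rmsds))
}

#' Write pooled ligand atoms as a PDB-format file
#'
#' @param pooled result of \code{\link{poolLigands}}.
#' @param path output file (HETATM records).
#' @return \code{path}, invisibly.
#' @export
writePooledLigands <- function(pooled, path) {
  a <- pooled$atoms
  if (nrow(a) == 0L) {
    writeLines("END", path)
    return(invisible(path))
  }
  s <- new("ProteinStructure", id = "pooled", atoms = data.frame(
    chain = "L", resno = as.integer(factor(a$structure)), ins = "",
    resname = substr(a$resname, 1, 3), atom = a$atom,
    element = substr(a$atom, 1, 1), x = a$x, y = a$y, z = a$z, het = TRUE,
    stringsAsFactors = FALSE))
  writeStructure(s, path)
}
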