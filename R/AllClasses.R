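#' @import methods
NULL

#' ProteinStructure: an atomic model
#'
#' Container for a parsed coordinate file. Atoms live in a single data.frame
#' (one row per atom) with author residue numbering; polymer (amino-acid)
#' residues are distinguished from hetero (ligand candidate) residues by the
#' \code{het} flag. Waters are dropped at parse time by default and alternate
#' locations are resolved to the highest-occupancy conformer.
#'
#' @slot id single character identifier.
#' @slot atoms data.frame with columns \code{chain}, \code{resno} (integer,
#'   author numbering), \code{ins} (insertion code, "" if none),
#'   \code{resname}, \code{atom} (atom name, e.g. "CA"), \code{element},
#'   \code{x}, \code{y}, \code{z} (Angstrom), \code{het} (logical).
#'
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(id = "character", atoms = "data.frame"))

setValidity("ProteinStructure", function(object) {
  need <- c("chain", "resno", "ins", "resname", "atom", "element",
            "x", "y", "z", "het")
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "id must be length 1")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  else {
    a <- object@atoms
    if (nrow(a) == 0L) msg <- c(msg, "structure has no atoms")
    # polymer residues must expose a CA and be strictly ordered within chains
    pol <- a[!a$het, , drop = FALSE]
    if (nrow(pol) > 0L) {
      key <- paste(pol$chain, pol$resno, pol$ins)
      has_ca <- tapply(pol$atom, key, function(x) "CA" %in% x)
      if (!all(has_ca))
        msg <- c(msg, "every polymer residue must have a CA atom")
      for (ch in unique(pol$chain)) {
        rn <- pol$resno[pol$chain == ch]
        ic <- pol$ins[pol$chain == ch]
        o <- order(match(paste(rn, ic), unique(paste(rn, ic))))
        u <- !duplicated(paste(rn, ic))
        rk <- rn[u] + match(ic[u], c("", LETTERS)) / 100
        if (is.unsorted(rk))
          msg <- c(msg, sprintf("chain %s residues not in increasing order", ch))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' DomainRange: an ECOD-style residue range
#'
#' One or more inclusive segments of author residue numbers on named chains,
#' as written in ECOD range strings such as \code{"A:1-170"}.
#'
#' @slot segments data.frame with columns \code{chain}, \code{start},
#'   \code{end} (integers, inclusive).
#' @exportClass DomainRange
setClass("DomainRange", representation(segments = "data.frame"))

setValidity("DomainRange", function(object) {
  s <- object@segments
  if (!all(c("chain", "start", "end") %in% names(s)))
    return("segments needs chain/start/end columns")
  if (nrow(s) == 0L) return("segments must be non-empty")
  if (any(s$start > s$end)) return("segment start must be <= end")
  TRUE
})

#' SSESet: assigned secondary-structure elements
#'
#' Sequence-ordered helix/strand segments of one structure, each with a
#' least-squares axis fitted through its CA atoms.
#'
#' @slot elements data.frame with one row per SSE: \code{index}, \code{kind}
#'   ("helix"/"strand"), \code{chain}, \code{start}, \code{end} (author resno),
#'   \code{nres}.
#' @slot axes numeric matrix (n x 9): unit axis vector (ax,ay,az), start point
#'   and end point of the fitted axis, rows aligned with \code{elements}.
#' @slot residues list of integer vectors (author residue numbers) per SSE.
#' @slot structureId id of the structure the assignment came from.
#' @exportClass SSESet
setClass("SSESet",
  representation(elements = "data.frame", axes = "matrix",
                 residues = "list", structureId = "character"))

setValidity("SSESet", function(object) {
  n <- nrow(object@elements)
  if (n != length(object@residues)) return("residues list length mismatch")
  if (n > 0L && (nrow(object@axes) != n || ncol(object@axes) != 9L))
    return("axes must be n x 9")
  if (n > 0L) {
    nrm <- sqrt(rowSums(object@axes[, 1:3, drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6)) return("axis vectors must have unit norm")
    if (!all(object@elements$kind %in% c("helix", "strand")))
      return("kind must be helix or strand")
  }
  TRUE
})

#' InteractionMatrix: pairwise SSE relations
#'
#' For every ordered SSE pair, a relation code: \code{P}/\code{A} for
#' parallel/antiparallel hydrogen-bonded strand pairs, \code{C}/\code{T} for
#' packing contacts (crossing angle near-collinear vs. angled), or
#' \code{none}. Helix-strand contacts additionally carry a side sign (+1/-1)
#' relative to the sheet plane fitted through all strand CA atoms.
#'
#' @slot codes character matrix (n x n), symmetric.
#' @slot sides numeric matrix (n x n), +1/-1 for helix-strand C/T entries,
#'   NA elsewhere.
#' @slot angles numeric matrix of crossing angles in degrees (0..180).
#' @slot sse the SSESet the matrix was built for.
#' @exportClass InteractionMatrix
setClass("InteractionMatrix",
  representation(codes = "matrix", sides = "matrix", angles = "matrix",
                 sse = "SSESet"))

setValidity("InteractionMatrix", function(object) {
  cd <- object@codes
  if (nrow(cd) != ncol(cd)) return("codes must be square")
  if (!identical(cd, t(cd))) return("codes must be symmetric")
  if (!all(cd %in% c("none", "P", "A", "C", "T")))
    return("invalid relation code")
  k <- object@sse@elements$kind
  if (length(k) == nrow(cd)) {
    pa <- cd %in% c("P", "A")
    dim(pa) <- dim(cd)
    bad <- which(pa, arr.ind = TRUE)
    if (nrow(bad) > 0L &&
        !all(k[bad[, 1]] == "strand" & k[bad[, 2]] == "strand"))
      return("P/A codes allowed only between two strands")
  }
  TRUE
})

#' RLMMatch: one minimal Rossmann-like motif instance
#'
#' Residue ranges of motif elements I (beta1), II (alpha1), III (beta2),
#' IV (crossover helix/strand, possibly absent) and V (beta3), plus the
#' catalytic loop (between I and II) and the crossover loop (immediately
#' N-terminal of element IV).
#'
#' @slot structureId character.
#' @slot domainId character ("" until assigned).
#' @slot variant one of "helix-IV", "strand-IV", "loop-IV".
#' @slot elements named list (I, II, III, IV, V) of integer residue-number
#'   vectors; IV may be empty.
#' @slot catalyticLoop integer residue numbers (possibly empty).
#' @slot crossoverLoop integer residue numbers (possibly empty).
#' @slot chain chain id the motif lives on.
#' @slot sseIndices named integer vector of SSE indices used per element.
#' @slot flags character vector of annotations (e.g. "secondary" when a domain
#'   holds more than one match).
#' @exportClass RLMMatch
setClass("RLMMatch",
  representation(structureId = "character", domainId = "character",
                 variant = "character", elements = "list",
                 catalyticLoop = "integer", crossoverLoop = "integer",
                 chain = "character", sseIndices = "integer",
                 flags = "character"))

setValidity("RLMMatch", function(object) {
  if (!object@variant %in% c("helix-IV", "strand-IV", "loop-IV"))
    return("invalid variant")
  el <- object@elements
  if (!all(c("I", "II", "III", "IV", "V") %in% names(el)))
    return("elements must be named I..V")
  for (e in c("I", "III", "V"))
    if (length(el[[e]]) < 3L)
      return(sprintf("element %s must have >= 3 residues", e))
  starts <- vapply(el[c("I", "II", "III", "V")], min, numeric(1))
  if (is.unsorted(starts, strictly = TRUE))
    return("elements must be in sequence order")
  TRUE
})

#' ConservationProfile: per-column conservation of an MSA
#'
#' Column-wise negated Shannon entropy of amino-acid frequencies (gaps
#' excluded), z-scored across scored columns so that higher means more
#' conserved and the profile is centred. Columns with more than 50 percent
#' gaps are unscored (NA).
#'
#' @slot values numeric per alignment column (NA where unscored).
#' @slot refResno integer: author residue number of the reference sequence at
#'   each column (NA at reference-gap columns).
#' @slot refRow which alignment row anchors the residue mapping.
#' @slot normalized logical.
#' @exportClass ConservationProfile
setClass("ConservationProfile",
  representation(values = "numeric", refResno = "integer",
                 refRow = "integer", normalized = "logical"))

setValidity("ConservationProfile", function(object) {
  if (length(object@values) != length(object@refResno))
    return("values and refResno must align")
  v <- object@values[!is.na(object@values)]
  if (object@normalized && length(v) > 1L) {
    if (abs(mean(v)) > 1e-9) return("normalized profile must have mean 0")
    if (abs(stats::sd(v) - 1) > 1e-9) return("normalized profile must have sd 1")
  }
  TRUE
})

#' BinnedProfile: element-wise binned conservation
#'
#' Per RLM element, a fixed number of bins holding a conservation value each;
#' aggregation across many profiles adds a standard error per bin.
#'
#' @slot binCounts named integer vector (one per element).
#' @slot means named list of numeric vectors, one per element.
#' @slot se named list of numeric vectors (0 for a single profile).
#' @slot n number of profiles aggregated.
#' @exportClass BinnedProfile
setClass("BinnedProfile",
  representation(binCounts = "integer", means = "list", se = "list",
                 n = "integer"))

setValidity("BinnedProfile", function(object) {
  if (!identical(names(object@binCounts), names(object@means)))
    return("binCounts and means must share element names")
  if (any(object@binCounts < 1L)) return("bin counts must be >= 1")
  for (e in names(object@means)) {
    if (length(object@means[[e]]) != object@binCounts[[e]])
      return("means length must equal bin count")
    if (any(object@se[[e]] < 0, na.rm = TRUE)) return("SE must be >= 0")
  }
  TRUE
})

#' Superposition: a rigid-body fit
#'
#' Result of a Kabsch least-squares superposition: proper rotation,
#' translation, the residual RMSD over the correspondence, and its length.
#' Transformed coordinates are \code{x R^T + t} (row vectors).
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric (Angstrom).
#' @slot rmsd numeric.
#' @slot n correspondence length (atoms).
#' @exportClass Superposition
setClass("Superposition",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", n = "integer"))

setValidity("Superposition", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation must be orthonormal")
  if (abs(det(R) - 1) > 1e-8) return("rotation must be proper (det +1)")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  pol <- a[!a$het, ]
  het <- a[a$het, ]
  cat("ProteinStructure '", object@id, "': ",
      length(unique(pol$chain)), " chain(s), ",
      length(unique(paste(pol$chain, pol$resno, pol$ins))),
      " polymer residues, ",
      length(unique(paste(het$chain, het$resno, het$ins, het$resname))),
      " hetero residues, ", nrow(a), " atoms\n", sep = "")
})

setMethod("show", "SSESet", function(object) {
  cat("SSESet for '", object@structureId, "': ",
      nrow(object@elements), " elements (",
      sum(object@elements$kind == "strand"), " strands, ",
      sum(object@elements$kind == "helix"), " helices)\n", sep = "")
  if (nrow(object@elements)) print(object@elements, row.names = FALSE)
})

setMethod("show", "InteractionMatrix", function(object) {
  cat("InteractionMatrix (", nrow(object@codes), " SSEs)\n", sep = "")
  print(object@codes)
})

setMethod("show", "RLMMatch", function(object) {
  rng <- vapply(object@elements, function(r)
    if (length(r)) sprintf("%d-%d", min(r), max(r)) else "-", character(1))
  cat("RLMMatch [", object@variant, "] on ", object@structureId,
      if (nzchar(object@domainId)) paste0(" (domain ", object@domainId, ")"),
      "\n  ", paste(sprintf("%s:%s", names(rng), rng), collapse = "  "),
      "\n", sep = "")
})

setMethod("show", "Superposition", function(object) {
  cat(sprintf("Superposition: %d atoms, RMSD %.4f A\n", object@n, object@rmsd))
})
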