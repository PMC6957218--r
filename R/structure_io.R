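#' Read a PDB-format coordinate file
#'
#' Parses ATOM and HETATM records into a \linkS4class{ProteinStructure}.
#' Standard amino-acid residues in ATOM records become polymer residues;
#' everything else is a hetero (ligand candidate) residue. Waters are excluded
#' by default; alternate locations are resolved to the highest-occupancy
#' conformer; only the first NMR model is read.
#'
#' @param path path to a PDB-format file.
#' @param id structure identifier; defaults to the file name without extension.
#' @param keep_water keep water residues (HOH/WAT/DOD) as hetero residues.
#' @return a \linkS4class{ProteinStructure}.
#' @export
readStructure <- function(path, id = NULL, keep_water = FALSE) {
  if (!file.exists(path)) stop("cannot read coordinate file: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty structure: no atoms in ", path)
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = as.integer(a$resno),
    ins = ifelse(is.na(a$insert) | a$insert == " ", "", a$insert),
    resname = a$resid,
    atom = a$elety,
    element = .atom_element(a$elesy, a$elety),
    x = a$x, y = a$y, z = a$z,
    het = a$type == "HETATM" & !(a$resid %in% .aa3),
    occ = ifelse(is.na(a$o), 1, a$o),
    alt = ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE)
  # amino acids typed ATOM are polymer even if a rare het name sneaks in
  atoms$het[atoms$resname %in% .aa3 & a$type == "ATOM"] <- FALSE
  if (!keep_water)
    atoms <- atoms[!atoms$resname %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("empty structure: no non-water atoms in ", path)
  # resolve altLocs: keep highest occupancy per (residue, atom name)
  if (any(nzchar(atoms$alt))) {
    key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$resname, atoms$atom)
    ord <- order(key, -atoms$occ, atoms$alt)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  }
  atoms$occ <- NULL; atoms$alt <- NULL
  rownames(atoms) <- NULL
  new("ProteinStructure", id = id, atoms = atoms)
}

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")

.atom_element <- function(elesy, elety) {
  e <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  miss <- !nzchar(e)
  # fall back to the first alphabetic character of the atom name
  e[miss] <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                 sub("^[0-9]*", "", elety[miss])), 1, 1))
  e
}

#' Write a structure as a PDB-format file
#'
#' Minimal fixed-width writer for round-tripping generated fixtures and for
#' emitting pooled ligand coordinates.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(s, path) {
  stopifnot(is(s, "ProteinStructure"))
  a <- s@atoms
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  name <- vapply(a$atom, function(x)
    if (nchar(x) < 4L) sprintf(" %-3s", x) else sprintf("%-4s", x), character(1))
  lines <- sprintf("%s%5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)) %% 100000L, name, a$resname,
                   substr(a$chain, 1, 1), a$resno %% 10000L,
                   ifelse(nzchar(a$ins), a$ins, " "),
                   a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Parse an ECOD-style domain range string
#'
#' Range strings use the dialect \code{"CHAIN:START-END"} with multiple
#' comma-separated segments, e.g. \code{"A:1-170"} or \code{"A:5-40,A:90-120"}.
#' Negative residue numbers are allowed.
#'
#' @param text range string.
#' @return a \linkS4class{DomainRange}.
#' @export
parseDomainRange <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(trimws(text), ",", fixed = TRUE)[[1]]
  if (length(parts) == 0L) stop("empty range string")
  pat <- "^([A-Za-z0-9]+):(-?[0-9]+)[-–](-?[0-9]+)$"
  segs <- lapply(parts, function(p) {
    p <- trimws(p)
    m <- regmatches(p, regexec(pat, p))[[1]]
    if (length(m) != 4L)
      stop("malformed range segment: '", p, "'")
    data.frame(chain = m[2], start = as.integer(m[3]), end = as.integer(m[4]),
               stringsAsFactors = FALSE)
  })
  new("DomainRange", segments = do.call(rbind, segs))
}

#' Format a DomainRange back to its string form
#' @param r a \linkS4class{DomainRange}.
#' @return character scalar.
#' @export
formatDomainRange <- function(r) {
  stopifnot(is(r, "DomainRange"))
  paste(sprintf("%s:%d-%d", r@segments$chain, r@segments$start,
                r@segments$end), collapse = ",")
}

#' Residues of a structure falling inside a domain range
#'
#' Returns the duplicate-free union of polymer residues whose (chain, number)
#' fall inside any segment, ordered as they appear along the chains.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param r a \linkS4class{DomainRange}.
#' @return data.frame with columns \code{chain}, \code{resno}, \code{ins},
#'   \code{resname}, one row per residue.
#' @export
residuesInRange <- function(s, r) {
  stopifnot(is(s, "ProteinStructure"), is(r, "DomainRange"))
  a <- s@atoms[!s@atoms$het, , drop = FALSE]
  missing <- setdiff(r@segments$chain, a$chain)
  if (length(missing))
    stop("chain(s) not present in structure: ", paste(missing, collapse = ", "))
  res <- a[!duplicated(paste(a$chain, a$resno, a$ins)),
           c("chain", "resno", "ins", "resname"), drop = FALSE]
  keep <- rep(FALSE, nrow(res))
  for (i in seq_len(nrow(r@segments))) {
    sg <- r@segments[i, ]
    keep <- keep | (res$chain == sg$chain & res$resno >= sg$start &
                    res$resno <= sg$end)
  }
  out <- res[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# residue-level helpers shared across modules ------------------------------

# per-residue table (polymer only, one row per residue, in chain order)
.residue_table <- function(s) {
  a <- s@atoms[!s@atoms$het, , drop = FALSE]
  a[!duplicated(paste(a$chain, a$resno, a$ins)),
    c("chain", "resno", "ins", "resname"), drop = FALSE]
}

# coordinates of a named atom for a set of residues (NA rows when absent)
.atom_xyz <- function(s, chain, resno, atom = "CA") {
  a <- s@atoms
  idx <- match(paste(chain, resno, atom),
               paste(a$chain, a$resno, a$atom))
  cbind(a$x[idx], a$y[idx], a$z[idx])
}

# all heavy-atom coordinates of given residues of one chain
.heavy_xyz <- function(s, chain, resnos, het = FALSE) {
  a <- s@atoms
  sel <- a$chain == chain & a$resno %in% resnos & a$het == het &
    a$element != "H"
  as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
}
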