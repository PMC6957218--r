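# Fixture generation is deterministic but not free; build each one once per
# test run.
.fx_cache <- new.env(parent = emptyenv())

fx <- function(name) {
  if (!exists(name, envir = .fx_cache)) {
    val <- switch(name,
      ideal = makeIdealRLM(),
      ideal_lig = makeIdealRLM(ligand = TRUE),
      strand_iv = makeIdealRLM(variant = "strand-IV"),
      loop_iv = makeIdealRLM(variant = "loop-IV"),
      insertion = makeIdealRLM(insertion = TRUE),
      angle60 = makeIdealRLM(helix_angle_II = 60),
      decoy_antiparallel_V = makeDecoy("antiparallel_V"),
      decoy_short_strand = makeDecoy("short_strand"),
      decoy_no_crossover = makeDecoy("no_crossover"),
      decoy_same_face_helices = makeDecoy("same_face_helices"),
      stop("unknown fixture ", name))
    assign(name, val, envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

scan_of <- function(name) {
  key <- paste0("scan_", name)
  if (!exists(key, envir = .fx_cache))
    assign(key, scanStructure(fx(name)$structure), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

# rigid-body transform of a ProteinStructure
transform_structure <- function(s, R, t, id = paste0(s@id, "_moved")) {
  a <- s@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  new("ProteinStructure", id = id, atoms = a)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, fixed to det +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
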