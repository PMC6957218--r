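# minimal structure: a handful of protein atoms plus one ligand atom at a
# controlled distance
contact_probe <- function(dist) {
  atoms <- rbind(
    data.frame(chain = "A", resno = 1:3, ins = "", resname = "GLY",
               atom = "CA", element = "C", x = c(0, 3.8, 7.6), y = 0, z = 0,
               het = FALSE, stringsAsFactors = FALSE),
    data.frame(chain = "A", resno = 101, ins = "", resname = "XYZ",
               atom = "C1", element = "C", x = 0, y = dist, z = 0,
               het = TRUE, stringsAsFactors = FALSE))
  new("ProteinStructure", id = "probe", atoms = atoms)
}

test_that("the 4 A cutoff separates contact from no contact", {
  ct <- findContacts(contact_probe(3.9))
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$ligand, "XYZ")
  expect_equal(ct$min_dist, 3.9, tolerance = 1e-9)
  expect_equal(nrow(findContacts(contact_probe(4.1))), 0L)
})

test_that("contacts at a smaller cutoff are a subset of a larger one", {
  s <- fx("ideal_lig")$structure
  m <- scan_of("ideal")$matches[[1]]
  for (cuts in list(c(3, 4), c(4, 6), c(2, 8))) {
    c1 <- findContacts(s, match = m, cutoff = cuts[1])
    c2 <- findContacts(s, match = m, cutoff = cuts[2])
    key <- function(x) paste(x$ligand, x$chain, x$resno)
    expect_true(all(key(c1) %in% key(c2)))
  }
})

test_that("crevice ligand contacts attribute the flanking motif regions", {
  fxl <- fx("ideal_lig")
  scan <- scanStructure(fxl$structure)
  m <- scan$matches[[1]]
  ct <- findContacts(fxl$structure, match = m)
  expect_equal(nrow(ct), 1L)
  got <- sort(strsplit(ct$elements, ",")[[1]])
  expect_equal(got, sort(c("I", "V", "catalytic_loop")))
  # brute-force all-pairs verification of the attribution
  a <- fxl$structure@atoms
  lig <- as.matrix(a[a$het, c("x", "y", "z")])
  regions <- c(m@elements, list(catalytic_loop = m@catalyticLoop,
                                crossover_loop = m@crossoverLoop))
  for (e in names(regions)) {
    r <- regions[[e]]
    if (length(r) == 0L) next
    P <- as.matrix(a[!a$het & a$resno %in% r, c("x", "y", "z")])
    dmin <- min(sqrt(outer(rowSums(lig^2), rowSums(P^2), "+") -
                       2 * lig %*% t(P)))
    expect_equal(e %in% got, dmin <= 4, info = e)
  }
})

test_that("waters and blocklisted additives are excluded from contacts", {
  atoms <- rbind(
    contact_probe(3.0)@atoms,
    data.frame(chain = "A", resno = c(201, 202), ins = "",
               resname = c("HOH", "GOL"), atom = c("O", "C1"),
               element = c("O", "C"), x = 1, y = 1, z = 0, het = TRUE,
               stringsAsFactors = FALSE))
  s <- new("ProteinStructure", id = "probe2", atoms = atoms)
  ct <- findContacts(s)
  expect_equal(ct$ligand, "XYZ")
})

test_that("compound classification: override beats table beats fallback", {
  tax <- data.frame(compound = c("C00062", "C00063"),
                    kingdom = "Organic compounds",
                    superclass = c("Organic acids and derivatives",
                                   "Something else entirely"),
                    class = "Carboxylic acids and derivatives",
                    stringsAsFactors = FALSE)
  got <- classifyCompound(c("C00062", "C00063", "C05822", "C99999"), tax)
  expect_equal(got$superclass[1], "Organic acids and derivatives")
  expect_equal(got$source[1], "taxonomy-table")
  # CTP derivatives override the table
  expect_equal(got$superclass[2], "Nucleosides, nucleotides, and analogues")
  expect_equal(got$source[2], "manual-override")
  expect_equal(got$superclass[3], "Nucleosides, nucleotides, and analogues")
  # unknowns fall back to the generic group; classification is total
  expect_equal(got$superclass[4], "Generic compounds")
  expect_equal(got$source[4], "generic-fallback")
  expect_false(anyNA(got$superclass))
  # deterministic
  expect_identical(got, classifyCompound(c("C00062", "C00063", "C05822",
                                           "C99999"), tax))
})

test_that("biological significance follows substrate/product/cofactor sets", {
  subs <- data.frame(ec = "1.1.1.1", compound = "C00003")  # NAD
  prods <- data.frame(ec = "1.1.1.1", compound = "C00004")
  expect_equal(flagSignificance("C00003", "1.1.1.1", subs, prods),
               "significant")
  expect_equal(flagSignificance("C00116", "1.1.1.1", subs, prods),
               "uncertain")                     # glycerol: in no set
  expect_equal(flagSignificance("C00305", "1.1.1.1", subs, prods,
                                cofactors = "C00305"), "significant")
  expect_equal(flagSignificance(NA_character_, "1.1.1.1", subs, prods),
               "uncertain")
})

test_that("self-superposition is the identity with zero RMSD", {
  fxl <- fx("ideal")
  m <- scan_of("ideal")$matches[[1]]
  mem <- list(structure = fxl$structure, match = m)
  sp <- superposeRLM(mem, mem)
  expect_equal(sp@rmsd, 0, tolerance = 1e-9)
  expect_equal(sp@rotation, diag(3), tolerance = 1e-9)
  expect_equal(sp@translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("a constructed rigid transform is recovered below 1e-6 RMSD", {
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  t0 <- c(5, -2, 1)
  s <- fx("ideal")$structure
  m <- scan_of("ideal")$matches[[1]]
  moved <- transform_structure(s, R, t0)
  sp <- superposeRLM(list(structure = moved, match = m),
                     list(structure = s, match = m))
  expect_lt(sp@rmsd, 1e-6)
  # the recovered transform inverts the constructed one
  expect_equal(sp@rotation, t(R), tolerance = 1e-9)
  expect_equal(as.numeric(sp@rotation %*% t0 + sp@translation), c(0, 0, 0),
               tolerance = 1e-9)
})

test_that("no random rigid transform beats the Kabsch optimum", {
  s <- fx("ideal")$structure
  m1 <- scan_of("ideal")$matches[[1]]
  s2 <- fx("strand_iv")$structure
  m2 <- scan_of("strand_iv")$matches[[1]]
  sp <- superposeRLM(list(structure = s2, match = m2),
                     list(structure = s, match = m1))
  cor <- rlmscan:::.match_correspondence(m1, m2, s, s2)
  set.seed(99)
  best <- Inf
  for (k in 1:10000) {
    R <- random_rotation()
    moved <- cor$Q %*% t(R)
    tt <- colMeans(cor$P) - colMeans(moved)
    rmsd <- sqrt(mean(rowSums((sweep(moved, 2, tt, "+") - cor$P)^2)))
    best <- min(best, rmsd)
  }
  expect_lte(sp@rmsd, best + 1e-12)
})

test_that("an under-determined correspondence is refused", {
  s <- fx("ideal")$structure
  m <- scan_of("ideal")$matches[[1]]
  ghost <- m
  ghost@elements <- lapply(m@elements, function(r) r + 5000L)
  expect_error(superposeRLM(list(structure = s, match = ghost),
                            list(structure = s, match = m)),
               "under-determined")
})

test_that("pooled ligand clouds from rotated copies coincide", {
  fxl <- fx("ideal_lig")
  m <- scanStructure(fxl$structure)$matches[[1]]
  set.seed(7)
  members <- list(list(structure = fxl$structure, match = m))
  for (k in 2:3) {
    R <- random_rotation()
    members[[k]] <- list(
      structure = transform_structure(fxl$structure, R,
                                      stats::runif(3, -30, 30),
                                      id = paste0("copy", k)),
      match = m)
  }
  pool <- poolLigands(members)
  ref <- as.matrix(pool$atoms[pool$atoms$structure == fxl$structure@id,
                              c("x", "y", "z")])
  for (k in 2:3) {
    got <- as.matrix(pool$atoms[pool$atoms$structure == paste0("copy", k),
                                c("x", "y", "z")])
    expect_lt(max(sqrt(rowSums((got - ref)^2))), 1e-6)
  }
  expect_true(all(pool$rmsd$rmsd < 1e-6))
  # pooling is invariant to member order (up to row order)
  pool2 <- poolLigands(members[c(1, 3, 2)])
  a1 <- pool$atoms[order(pool$atoms$structure, pool$atoms$atom), ]
  a2 <- pool2$atoms[order(pool2$atoms$structure, pool2$atoms$atom), ]
  expect_equal(a1$x, a2$x, tolerance = 1e-9)
})

test_that("a non-superposable member is skipped with a warning", {
  fxl <- fx("ideal_lig")
  m <- scanStructure(fxl$structure)$matches[[1]]
  bad <- m
  bad@elements <- lapply(m@elements, function(r) r + 5000L)
  members <- list(list(structure = fxl$structure, match = m),
                  list(structure = fxl$structure, match = bad))
  expect_warning(pool <- poolLigands(members), "skipping")
  expect_equal(nrow(pool$rmsd), 1L)
  f <- tempfile(fileext = ".pdb")
  writePooledLigands(pool, f)
  expect_true(any(grepl("^HETATM", readLines(f))))
})
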