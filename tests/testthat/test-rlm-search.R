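test_that("the ideal motif gives exactly one helix-IV match on target", {
  scan <- scan_of("ideal")
  expect_length(scan$matches, 1L)
  m <- scan$matches[[1]]
  expect_equal(m@variant, "helix-IV")
  truth <- fx("ideal")$match
  for (e in c("I", "II", "III", "IV", "V")) {
    got <- m@elements[[e]]
    want <- truth@elements[[e]]
    expect_true(all(got %in% want),
                info = paste("element", e, "within designed range"))
    expect_gte(length(intersect(got, want)), min(3L, length(want)))
  }
  expect_true(length(m@catalyticLoop) >= 1L)
  expect_true(length(m@crossoverLoop) >= 1L)
})

test_that("strand-IV and loop-IV crossover variants are recognised", {
  m1 <- scan_of("strand_iv")$matches
  expect_length(m1, 1L)
  expect_equal(m1[[1]]@variant, "strand-IV")
  m2 <- scan_of("loop_iv")$matches
  expect_length(m2, 1L)
  expect_equal(m2[[1]]@variant, "loop-IV")
  expect_length(m2[[1]]@elements$IV, 0L)
  expect_gte(length(m2[[1]]@crossoverLoop), 2L)
})

test_that("each decoy family yields zero matches", {
  for (k in c("antiparallel_V", "short_strand", "no_crossover",
              "same_face_helices"))
    expect_length(scan_of(paste0("decoy_", k))$matches, 0L)
})

test_that("a beta-alpha insertion is tolerated and excluded from elements", {
  scan <- scan_of("insertion")
  expect_length(scan$matches, 1L)
  m <- scan$matches[[1]]
  expect_equal(m@variant, "helix-IV")
  # element V is the post-crossover strand (the last SSE), not the insertion
  expect_equal(unname(m@sseIndices[["V"]]), nrow(scan$sse@elements))
  # the insertion SSEs (between III and IV) are part of no element
  ins <- setdiff(seq_len(nrow(scan$sse@elements)), unname(m@sseIndices))
  expect_length(ins, 2L)
  expect_true(all(ins > m@sseIndices[["III"]] & ins < m@sseIndices[["V"]]))
})

test_that("matcher equals the clause-by-clause brute-force oracle", {
  for (name in c("ideal", "strand_iv", "loop_iv", "insertion", "angle60",
                 "decoy_antiparallel_V", "decoy_short_strand",
                 "decoy_no_crossover", "decoy_same_face_helices")) {
    scan <- scan_of(name)
    expect_lte(nrow(scan$sse@elements), 12L)
    expect_equal(match_signature(scan$matches),
                 oracle_signature(brute_force_rlm(scan$matrix,
                                                  scan$structure)),
                 info = name)
  }
})

test_that("identical input yields identical ordered matches", {
  s <- fx("ideal")$structure
  m1 <- scanStructure(s)$matches
  m2 <- scanStructure(s)$matches
  expect_identical(match_signature(m1), match_signature(m2))
  expect_identical(matchTable(m1), matchTable(m2))
})

test_that("adding a remote helix never removes a match", {
  s <- fx("ideal")$structure
  far <- rlmscan:::.transform_segment(
    rlmscan:::.canonical_segment(rlmscan:::.build_segment(10, -57, -47)),
    t = c(0, 0, 60))
  rows <- list()
  base <- max(s@atoms$resno) + 10L
  for (i in seq_along(far)) {
    res <- far[[i]]
    rows[[i]] <- data.frame(
      chain = "A", resno = base + i, ins = "", resname = "GLY",
      atom = rownames(res), element = substr(rownames(res), 1, 1),
      x = res[, 1], y = res[, 2], z = res[, 3], het = FALSE,
      stringsAsFactors = FALSE)
  }
  s2 <- new("ProteinStructure", id = "augmented",
            atoms = rbind(s@atoms, do.call(rbind, rows)))
  scan2 <- scanStructure(s2)
  expect_equal(nrow(scan2$sse@elements), 6L)
  expect_length(scan2$matches, length(scan_of("ideal")$matches))
})

test_that("domain anchoring keeps only fully contained matches", {
  scan <- scan_of("ideal")
  m <- scan$matches
  dom_all <- data.frame(id = "d1", range = fx("ideal")$domain,
                        stringsAsFactors = FALSE)
  kept <- assignToDomain(m, dom_all)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]@domainId, "d1")
  # a domain ending before element V discards the match
  vstart <- min(m[[1]]@elements$V)
  dom_cut <- data.frame(id = "d2",
                        range = sprintf("A:1-%d", vstart - 1L),
                        stringsAsFactors = FALSE)
  expect_length(assignToDomain(m, dom_cut), 0L)
})

test_that("two matches in one domain are both kept and flagged", {
  s <- fx("ideal")$structure
  shift <- max(s@atoms$resno) + 20L
  a2 <- s@atoms
  a2$resno <- a2$resno + shift
  a2$x <- a2$x + 80
  s2 <- new("ProteinStructure", id = "tandem", atoms = rbind(s@atoms, a2))
  scan <- scanStructure(s2)
  expect_length(scan$matches, 2L)
  n <- max(s2@atoms$resno)
  kept <- assignToDomain(scan$matches,
                         data.frame(id = "big", range = sprintf("A:1-%d", n),
                                    stringsAsFactors = FALSE))
  expect_length(kept, 2L)
  flags <- vapply(kept, function(m) m@flags[1], character(1))
  expect_setequal(flags, c("canonical", "secondary"))
  starts <- vapply(kept, function(m) min(m@elements$I), numeric(1))
  expect_equal(flags[which.min(starts)], "canonical")
  # with one domain per copy, each match lands in its own domain
  doms <- data.frame(id = c("dA", "dB"),
                     range = c(sprintf("A:1-%d", shift),
                               sprintf("A:%d-%d", shift + 1L, n)),
                     stringsAsFactors = FALSE)
  kept2 <- assignToDomain(scan$matches, doms)
  expect_setequal(vapply(kept2, function(m) m@domainId, character(1)),
                  c("dA", "dB"))
})
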