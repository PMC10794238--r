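test_that("PDB reading keeps heavy atoms, resolves altlocs, drops HETATM", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(f)
  s <- read_structure(f)
  expect_equal(nrow(s$residues), 3L)
  expect_equal(s$residues$aa, c("A", "L", "G"))
  # hydrogen dropped, altloc B dropped, water dropped: 2 + 1 + 1 atoms
  expect_equal(nrow(s$atoms), 4L)
  # altloc resolved to the highest-occupancy conformer (x = 4.5)
  expect_equal(s$atoms$x[s$atoms$resno == 2], 4.5)
  expect_error(read_structure(f, chains = "Z"), "selection error")
})

test_that("contact map matches a brute-force all-atom double loop", {
  set.seed(5)
  # 8 residues, 2 atoms each, hand-jittered cluster
  xyz <- matrix(runif(16 * 3, 0, 12), 16, 3)
  at <- data.frame(chain = "A", resno = rep(1:8, each = 2), aa = "A",
                   elety = rep(c("CA", "CB"), 8),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  s <- protein_structure(at)
  cm <- build_contact_map(s, cutoff = 5.0, min_sep = 2L)

  # oracle: O(n^2 m^2) explicit loop
  expected <- list()
  for (i in 1:7) for (j in (i + 1):8) {
    if (j - i < 2) next
    ai <- as.matrix(at[at$resno == i, c("x", "y", "z")])
    aj <- as.matrix(at[at$resno == j, c("x", "y", "z")])
    dmin <- Inf
    for (p in 1:2) for (q in 1:2)
      dmin <- min(dmin, sqrt(sum((ai[p, ] - aj[q, ])^2)))
    if (dmin < 5.0) expected[[length(expected) + 1]] <- c(i, j, dmin)
  }
  exp_mat <- do.call(rbind, expected)
  expect_equal(nrow(cm$contacts), nrow(exp_mat))
  expect_equal(cm$contacts$i, exp_mat[, 1])
  expect_equal(cm$contacts$j, exp_mat[, 2])
  expect_equal(cm$contacts$min_distance, exp_mat[, 3])
})

test_that("sequence-adjacent residues never contact; cutoff is monotone", {
  xyz <- cbind(seq(0, 28, by = 4), 0, 0)   # collinear CA trace
  s <- structure_from_coords(xyz)
  cm <- build_contact_map(s, cutoff = 5.0)
  expect_equal(nrow(cm$contacts), 0L)      # |i-j|=1 pairs are 4 A apart
  cm9 <- build_contact_map(s, cutoff = 9.0)
  expect_true(all(abs(cm9$contacts$i - cm9$contacts$j) >= 2))
  # increasing cutoff never removes contacts
  key5 <- paste(cm$contacts$i, cm$contacts$j)
  key9 <- paste(cm9$contacts$i, cm9$contacts$j)
  expect_true(all(key5 %in% key9))
})

test_that("contact map is stable under atom-order permutation", {
  toy <- make_toy_structure(12, seed = 2)
  at <- toy$structure$atoms[, c("chain", "resno", "aa", "elety",
                                "x", "y", "z")]
  set.seed(1)
  s2 <- protein_structure(at[sample(nrow(at)), ])
  cm2 <- build_contact_map(s2)
  expect_equal(cm2$contacts[, c("i", "j")],
               toy$cmap$contacts[, c("i", "j")])
})

test_that("sequence energy equals a naive double loop and is additive", {
  em <- mj_energy_model()
  expect_equal(sequence_energy("ACD", cmap_from_pairs(matrix(0, 0, 2), 3),
                               em), 0)
  cm <- cmap_from_pairs(rbind(c(1, 3)), 3)
  expect_equal(sequence_energy("LVL", cm, em), em$table["L", "L"])

  set.seed(8)
  toy <- make_toy_structure(30, seed = 4)
  seq <- sample(AA, 30, replace = TRUE)
  cmap <- toy$cmap
  naive <- 0
  for (r in seq_len(nrow(cmap$contacts)))
    naive <- naive + em$table[seq[cmap$contacts$i[r]],
                              seq[cmap$contacts$j[r]]]
  expect_equal(sequence_energy(seq, cmap, em), unname(naive))

  # additivity over a partition of the contact set
  half <- seq_len(nrow(cmap$contacts) %/% 2)
  cm_a <- cmap; cm_a$contacts <- cmap$contacts[half, ]
  cm_b <- cmap; cm_b$contacts <- cmap$contacts[-half, ]
  expect_equal(sequence_energy(seq, cm_a, em) +
                 sequence_energy(seq, cm_b, em),
               sequence_energy(seq, cmap, em))
  expect_error(sequence_energy(c("B", "A", "C"), cm, em), "alphabet")
})

test_that("complex energy partitions into E1 + E2 + E12", {
  em <- mj_energy_model()
  toy <- make_toy_structure(14, chains = 2, seed = 6)
  set.seed(2)
  sr <- sample(AA, 14, replace = TRUE)
  sh <- sample(AA, 14, replace = TRUE)
  ce <- complex_energy(sr, sh, toy$cmap, em)
  full <- c(sr, sh)
  brute <- c(E1 = 0, E2 = 0, E12 = 0)
  for (r in seq_len(nrow(toy$cmap$contacts))) {
    ct <- toy$cmap$contacts[r, ]
    e <- em$table[full[ct$i], full[ct$j]]
    lab <- switch(ct$partition, intra_A = "E1", intra_B = "E2",
                  inter = "E12")
    brute[lab] <- brute[lab] + e
  }
  expect_equal(ce$E1, unname(brute["E1"]))
  expect_equal(ce$E2, unname(brute["E2"]))
  expect_equal(ce$E12, unname(brute["E12"]))
  expect_equal(ce$E, sum(brute))
  # rigid mode: total equals the inter term
  expect_equal(complex_energy(sr, sh, toy$cmap, em, rigid = TRUE)$E,
               ce$E12)
  # decoys differing only in inter contacts differ by their E12
  no_inter <- subset_contacts(toy$cmap, c("intra_A", "intra_B"))
  ce0 <- complex_energy(sr, sh, no_inter, em)
  expect_equal(ce0$E12, 0)
  expect_equal(ce$E - ce0$E, ce$E12)
})

test_that("pair_min_distance equals brute force over atom pairs", {
  toy <- make_toy_structure(10, seed = 9)
  s <- toy$structure
  expect_equal(pair_min_distance(s, 4, 4), 0)
  a <- as.matrix(s$atoms[s$atoms$res_index == 2, c("x", "y", "z")])
  b <- as.matrix(s$atoms[s$atoms$res_index == 7, c("x", "y", "z")])
  dmin <- Inf
  for (p in seq_len(nrow(a))) for (q in seq_len(nrow(b)))
    dmin <- min(dmin, sqrt(sum((a[p, ] - b[q, ])^2)))
  expect_equal(pair_min_distance(s, 2, 7), dmin)
  # single-atom residues at a known distance
  s2 <- structure_from_coords(rbind(c(0, 0, 0), c(7.5, 0, 0)))
  expect_equal(pair_min_distance(s2, 1, 2), 7.5)
})

test_that("alignment columns map monotonically onto structure residues", {
  toy <- make_toy_structure(10, seed = 1)
  s <- toy$structure
  s$residues$aa <- AA[1:10]
  s$atoms$aa <- rep(AA[1:10], 2)[order(rep(1:10, 2))]
  # identity case: consensus equals the chain sequence
  aln <- aln_from_strings(rep(paste0(AA[1:10], collapse = ""), 5),
                          list(Rec = c(0L, 10L)))
  map <- map_alignment_to_structure(aln, s, c(Rec = "A"))
  expect_equal(map$res_index, 1:10)
  # structure missing two residues: those columns unmapped, rest intact
  s2 <- s
  s2$atoms <- s2$atoms[!s2$atoms$res_index %in% c(4, 5), ]
  s2 <- protein_structure(s2$atoms[, c("chain", "resno", "aa", "elety",
                                       "x", "y", "z")])
  map2 <- map_alignment_to_structure(aln, s2, c(Rec = "A"))
  expect_true(all(is.na(map2$res_index[4:5])))
  expect_equal(map2$res_index[c(1:3, 6:10)],
               c(1:3, 4:8))
})
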