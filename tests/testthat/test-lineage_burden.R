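test_that("burden proportions follow the 1/2/3/>3 binning", {
  cells <- read_cell_metadata(data.frame(
    cell_id = sprintf("c%03d", 1:150), patient_id = "P1",
    lineage = "myeloid", subtype = "mono"))
  ## 30 cells carry 1 mutation, 10 carry 2, 5 carry 5
  carriers1 <- sprintf("c%03d", 1:45)                   # mutation A
  carriers2 <- sprintf("c%03d", 31:45)                  # mutations B..
  calls <- data.frame(locus = c("L1", "L2", "L3", "L4", "L5"))
  calls$carriers <- list(carriers1, carriers2,
                         sprintf("c%03d", 41:45), sprintf("c%03d", 41:45),
                         sprintf("c%03d", 41:45))
  bp <- burden_profile(calls, cells)
  expect_equal(bp$n_cells, 150L)
  expect_equal(bp$prop_1, 30 / 150)
  expect_equal(bp$prop_2, 10 / 150)
  expect_equal(bp$prop_3, 0)
  expect_equal(bp$prop_gt3, 5 / 150)
  ## bins plus the zero fraction partition the group exactly
  expect_equal(bp$prop_0 + bp$prop_1 + bp$prop_2 + bp$prop_3 + bp$prop_gt3,
               1)
})

test_that("groups under the minimum cell count are excluded", {
  cells <- read_cell_metadata(data.frame(
    cell_id = sprintf("c%03d", 1:180),
    patient_id = "P1",
    lineage = rep(c("myeloid", "fibroblast"), c(100, 80)),
    subtype = "s"))
  calls <- data.frame(locus = "L1")
  calls$carriers <- list(c("c001", "c002"))
  bp <- burden_profile(calls, cells)
  expect_equal(bp$lineage, "myeloid")
})

test_that("mutation matrix applies DEG exclusion and drops empty rows", {
  cells <- read_cell_metadata(data.frame(
    cell_id = sprintf("c%02d", 1:9), patient_id = "P1", lineage = "myeloid",
    subtype = rep(c("mono", "macro", "dc"), each = 3)))
  calls <- data.frame(locus = c("L1", "L2", "L3"),
                      gene = c("GENE1", "MARKER1", "GENE2"))
  calls$carriers <- list(c("c01", "c04"),  # mono + macro
                         c("c02"),         # in a DEG list: excluded
                         character())      # no carriers: all-zero, dropped
  deg <- list(mono = c("MARKER1", "OTHER"))
  mat <- build_mutation_matrix(calls, cells, deg_lists = deg)
  expect_equal(rownames(mat), "L1")
  expect_equal(as.integer(mat["L1", c("mono", "macro", "dc")]),
               c(1L, 1L, 0L))
  expect_equal(attr(mat, "excluded"), "L2")
  ## presence needs just one carrier cell by default
  expect_equal(sum(mat), 2L)
})

test_that("binary distance is the asymmetric-binary convention", {
  mat <- rbind(m1 = c(a = 1, b = 0), m2 = c(a = 1, b = 1),
               m3 = c(a = 1, b = 1), m4 = c(a = 0, b = 1))
  d <- binary_distance(mat)
  expect_equal(d["a", "b"], 2 / 4)
  expect_equal(diag(d), c(a = 0, b = 0))
  ident <- binary_distance(rbind(c(1, 1), c(0, 0), c(1, 1)))
  expect_equal(ident[1, 2], 0)
  disj <- binary_distance(rbind(c(1, 0), c(0, 1)))
  expect_equal(disj[1, 2], 1)
  ## empty union: no discordance observed
  empty <- binary_distance(matrix(0, 2, 2))
  expect_equal(empty[1, 2], 0)
})

test_that("binary distance is a metric on random binary matrices", {
  set.seed(77)
  for (i in 1:20) {
    mat <- matrix(rbinom(8 * 30, 1, 0.4), 30, 8,
                  dimnames = list(NULL, letters[1:8]))
    d <- binary_distance(mat)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    for (a in 1:8) for (b in 1:8) for (cc in 1:8)
      expect_lte(d[a, b], d[a, cc] + d[cc, b] + 1e-12)
  }
})

test_that("neighbor joining recovers additive topologies", {
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3 taxa")
  ## quartet ((A,B),(C,D)): within-pair distance 2, across 4
  d4 <- matrix(4, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d4) <- 0
  d4["A", "B"] <- d4["B", "A"] <- 2
  d4["C", "D"] <- d4["D", "C"] <- 2
  tr <- nj_tree(d4)
  expect_true(same_topology(tr, best_fit_topology(d4)))
  expect_true(same_topology(
    tr, ape::read.tree(text = "((A,B),(C,D));")))

  ## random additive matrices, 4-8 taxa, against the generating tree
  ## (and, for n = 4 and 5, against exhaustive topology enumeration)
  set.seed(42)
  for (n in 4:8) {
    for (rep in 1:3) {
      gen <- ape::rtree(n)
      gen$edge.length <- runif(nrow(gen$edge), 0.5, 2)
      d <- cophenetic(gen)
      tr <- nj_tree(d)
      expect_true(same_topology(tr, gen))
      if (n <= 5) expect_true(same_topology(tr, best_fit_topology(d)))
      expect_true(all(tr$edge.length >= 0))
    }
  }
})

test_that("degenerate equal distances resolve deterministically", {
  d <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  t1 <- nj_tree(d); t2 <- nj_tree(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("bootstrap gives full support to concordant clades and is stable", {
  mat <- rbind(matrix(rep(c(1, 1, 1, 0, 0, 0), 10), 10, byrow = TRUE),
               matrix(rep(c(0, 0, 0, 1, 1, 1), 8), 8, byrow = TRUE))
  dimnames(mat) <- list(paste0("m", 1:18),
                        c("A1", "A2", "A3", "B1", "B2", "B3"))
  tr <- bootstrap_support(mat, n_reps = 100, seed = 5)
  expect_true(all(attr(tr, "supports") == 100))
  ## determinism at fixed seed
  tr2 <- bootstrap_support(mat, n_reps = 100, seed = 5)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  ## invariance to mutation-row order
  perm <- mat[sample(nrow(mat)), ]
  tr3 <- bootstrap_support(perm, n_reps = 100, seed = 5)
  expect_identical(attr(tr, "supports"), attr(tr3, "supports"))
  ## a single mutation row still yields identical replicates
  one <- mat[1, , drop = FALSE]
  tr4 <- bootstrap_support(one, n_reps = 10, seed = 1)
  expect_true(all(attr(tr4, "supports") %in% c(0, 10)))
})

test_that("subtype tree on simulated clonal structure separates clades", {
  sim <- generous_sim()
  calls <- call_mutations(sim$acm, sim$cells, sim$genome, sim$masks)
  mat <- build_mutation_matrix(calls, sim$cells)
  st_lin <- unique(sim$cells[, c("subtype", "lineage")])
  tum <- st_lin$subtype[st_lin$lineage == "tumor"]
  mye <- st_lin$subtype[st_lin$lineage == "myeloid"]
  keep <- c(tum, mye)
  tr <- bootstrap_support(mat[, keep], n_reps = 50, seed = 3)
  ## tumor subtypes share truncal mutations: they must form one clade
  bip <- ape::prop.part(tr)
  labs <- attr(bip, "labels")
  sets <- lapply(bip, function(i) sort(labs[i]))
  expect_true(any(vapply(sets, function(s)
    identical(s, sort(tum)) || identical(s, sort(setdiff(keep, tum))),
    TRUE)))
})
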