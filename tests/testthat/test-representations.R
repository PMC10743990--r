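# Representation contracts, Tanimoto similarity, environment retro-map.

test_that("all seven kinds produce their fixed vector lengths", {
  sm <- c(a = "O=C(NCC)c1cc2cc(Cl)ccc2o1", b = "CCO",
          c = "CC(=O)Nc1ccc(O)cc1")
  expected <- c(morgan = 2048L, rdkit = 2048L, layered = 2048L,
                pattern = 2048L, pharm2d = 395L, pubchem = 881L,
                descriptors = 128L)
  for (k in names(expected)) {
    fm <- featurize(sm, k)
    expect_equal(ncol(featureData(fm)), unname(expected[[k]]))
    expect_equal(nrow(featureData(fm)), 3L)
    expect_equal(representationLength(k), unname(expected[[k]]))
  }
})

test_that("featurization is deterministic (bit-exact)", {
  sm <- c(x = "O=C(NCC)c1cc2cc(Br)ccc2o1", y = "CCN1CCOCC1")
  for (k in REPRESENTATION_KINDS) {
    f1 <- featureData(featurize(sm, k))
    f2 <- featureData(featurize(sm, k))
    expect_identical(f1, f2)
  }
})

test_that("ethanol's circular fingerprint matches the environment oracle", {
  # oracle: enumerate distinct atom environments of radius <= 2 by brute
  # force (distinct bond sets, plus one per atom at radius 0); each
  # environment sets one bit and ethanol is too small for collisions
  g <- consensusVS:::molgraph("CCO")
  bondsets <- character(0)
  for (a in seq_len(g$n)) for (r in 1:2) {
    ks <- which(pmin(g$dist[g$bonds$a, a], g$dist[g$bonds$b, a]) <= r - 1)
    bondsets <- c(bondsets, paste(sort(ks), collapse = ","))
  }
  n_env <- g$n + length(unique(bondsets))  # 3 radius-0 + distinct bond sets
  fp <- featurize(c(eth = "CCO"), "morgan")
  expect_equal(sum(featureData(fp)), n_env)
  expect_equal(sum(featureData(fp)), 6L)   # frozen: 3 atoms + 3 bond sets
})

test_that("tanimoto matches its set-arithmetic definition and properties", {
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto(c(1, 0), c(1, 0)), 1)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 1)   # both-empty convention
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "mismatch")

  set.seed(42)
  for (i in 1:50) {
    a <- rbinom(64, 1, runif(1, 0.1, 0.9))
    b <- rbinom(64, 1, runif(1, 0.1, 0.9))
    i_ <- sum(a == 1 & b == 1); u_ <- sum(a == 1 | b == 1)
    expect_equal(tanimoto(a, b), if (u_ == 0) 1 else i_ / u_)
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    expect_gte(tanimoto(a, b), 0); expect_lte(tanimoto(a, b), 1)
    if (sum(a) > 0) expect_equal(tanimoto(a, a), 1)
  }
})

test_that("tanimotoMatrix agrees with the scalar op", {
  A <- randomBits(6, 128, 1); B <- randomBits(4, 128, 2)
  S <- tanimotoMatrix(A, B)
  for (i in 1:6) for (j in 1:4)
    expect_equal(S[i, j], tanimoto(A[i, ], B[j, ]))
})

test_that("substructure kinds are monotone under disconnected duplication", {
  # appending a disconnected copy of a fragment can only add subgraphs,
  # so no on-bit of a substructure-type fingerprint may turn off
  base <- "CC(=O)Nc1ccc(O)cc1"
  dup <- paste0(base, ".", "c1ccc(O)cc1")
  for (k in c("pattern", "pubchem")) {
    b1 <- featureData(featurize(c(m = base), k))[1, ]
    b2 <- featureData(featurize(c(m = dup), k))[1, ]
    expect_true(all(b2[b1 == 1] == 1))
  }
})

test_that("retro-map inverts the circular fingerprint", {
  # benzene: one radius-0, one radius-1 and one radius-2 bit, each with
  # 6 symmetry-equivalent environments
  map <- retroMapBits("c1ccccc1")
  expect_equal(length(map), 3L)
  expect_true(all(vapply(map, `[[`, 0L, "n_occ") == 6L))
  for (m in map)
    expect_equal(length(m$environments), m$n_occ)

  # general molecule: atoms of every environment lie inside the molecule,
  # radius-0 environments are single atoms
  sm <- "O=C(NCC)c1cc2cc(Cl)ccc2o1"
  g <- consensusVS:::molgraph(sm)
  fp <- consensusVS:::morganFP(g)
  expect_true(all(unlist(lapply(fp$envs, `[[`, "atoms")) <= g$n))
  r0 <- Filter(function(e) e$radius == 0L, fp$envs)
  expect_true(all(lengths(lapply(r0, `[[`, "atoms")) == 1L))
  expect_equal(length(r0), g$n)
  # every on-bit is covered by the map and vice versa
  on <- which(fp$bits == 1L)
  expect_setequal(as.integer(names(retroMapBits(sm))), on)
})

test_that("descriptor vector is finite with pinned names", {
  d <- featureData(featurize(c(a = "CC(=O)Oc1ccccc1C(=O)O"), "descriptors"))
  expect_equal(colnames(d), descriptorNames())
  expect_true(all(is.finite(d)))
  expect_equal(length(descriptorNames()), 128L)
  # a few sanity anchors: aspirin has 13 heavy atoms, 1 ring, 1 COOH donor
  expect_equal(unname(d[1, "HeavyAtomCount"]), 13)
  expect_equal(unname(d[1, "RingCount"]), 1)
  expect_equal(unname(d[1, "HBondDonorCount"]), 1)
})
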