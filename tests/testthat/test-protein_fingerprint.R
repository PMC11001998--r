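# The fingerprint pipeline: neighborhoods -> dedup -> sorted keys ->
# stable hash -> on-bits, plus Jaccard similarity.

rigid_transform <- function(st, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- runif(3, -50, 50)
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% q
  st$atoms$x <- xyz[, 1] + shift[1]
  st$atoms$y <- xyz[, 2] + shift[2]
  st$atoms$z <- xyz[, 3] + shift[3]
  st
}

test_that("atom neighborhoods follow the radius and include the central residue", {
  # worked layout: central R at 27 close to F24, G25, F27; far E30
  coords <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 4),
                  c(20, 20, 20))
  st <- toy_structure(c("R", "F", "G", "F", "E"), coords,
                      numbers = c(27, 24, 25, 28, 30))
  nb <- atom_neighborhood(st, 1, radius = 5)
  expect_equal(nb$residue_code, c("F", "G", "R", "F"))
  expect_equal(nb$residue_number, c(24, 25, 27, 28))

  # isolated single residue: only itself, at any radius
  st1 <- toy_structure("G", matrix(c(1, 2, 3), ncol = 3))
  expect_equal(atom_neighborhood(st1, 1, radius = 0.1)$residue_code, "G")

  # two CA atoms 3.8 A apart: both in at r = 5, only self at r = 3
  st2 <- toy_structure(c("A", "V"), rbind(c(0, 0, 0), c(3.8, 0, 0)))
  expect_equal(nrow(atom_neighborhood(st2, 1, radius = 5.0)), 2)
  expect_equal(nrow(atom_neighborhood(st2, 1, radius = 3.0)), 1)
  expect_equal(nrow(atom_neighborhood(st2, 2, radius = 3.0)), 1)

  expect_error(atom_neighborhood(st2, 99, radius = 5), "not an atom")
})

test_that("per-atom neighborhoods are monotone in radius", {
  for (seed in 1:5) {
    st <- make_structure(40, seed = seed)
    for (i in c(1, 10, 25, 40)) {
      radii <- c(2, 4, 5, 7, 10)
      sizes <- vapply(radii, function(r)
        nrow(atom_neighborhood(st, i, radius = r)), integer(1))
      expect_true(all(diff(sizes) >= 0))
      # subset relation, not just size
      small <- atom_neighborhood(st, i, radius = 4)
      large <- atom_neighborhood(st, i, radius = 7)
      expect_true(all(small$residue_number %in% large$residue_number))
    }
  }
})

test_that("unique_patterns dedups shared member-sets and matches simple geometry", {
  # all atoms of one residue see the same neighbors -> one pattern
  st <- toy_structure(c("A", "A"), rbind(c(0, 0, 0), c(1, 0, 0)),
                      numbers = c(5, 5))
  expect_equal(length(unique_patterns(st, 5)), 1)

  # 3 residues on a line, spacing > 2r -> 3 singleton patterns
  st3 <- toy_structure(c("A", "C", "D"),
                       rbind(c(0, 0, 0), c(12, 0, 0), c(24, 0, 0)))
  pats <- unique_patterns(st3, radius = 5)
  expect_equal(pats, c("A1", "C2", "D3"))
})

test_that("grid neighbor search equals the brute-force oracle on random structures", {
  for (seed in 1:50) {
    n_res <- sample(30:200, 1)
    st <- make_structure(n_res, seed = seed)
    expect_identical(unique_patterns(st, 5, method = "grid"),
                     unique_patterns(st, 5, method = "brute"))
  }
})

test_that("pattern keys are sorted one-letter multisets", {
  expect_equal(encode_pattern("R23:F24:G25:F27"), "FFGR")
  expect_equal(encode_pattern(data.frame(residue_code = c("R", "F", "G", "F"),
                                         residue_number = c(23, 24, 25, 27))),
               "FFGR")
  expect_equal(encode_pattern("G10"), "G")
  expect_equal(encode_pattern("A5:A9"), "AA")  # duplicates preserved
  expect_error(encode_pattern(""), "character|empty")
})

test_that("hash is deterministic, in range, and matches frozen independent digests", {
  # FNV-1a 32-bit reference values computed with an independent
  # implementation
  expect_equal(hash_key(c("a", "G", "FFGR", "hello", "AAC", "WWWWY"), 16381),
               c(6717L, 3234L, 10118L, 10316L, 7883L, 15096L))
  set.seed(1)
  keys <- vapply(1:10000, function(i)
    paste(sample(LETTERS, sample(1:12, 1), replace = TRUE), collapse = ""),
    character(1))
  idx <- hash_key(keys, 16381)
  expect_true(all(idx >= 0 & idx < 16381))
  expect_identical(idx, hash_key(keys, 16381))
  expect_error(hash_key("", 16381), "empty")
})

test_that("collision rate at the default width matches the birthday bound", {
  set.seed(42)
  m <- 2000
  keys <- unique(vapply(seq_len(3 * m), function(i)
    paste(sample(LETTERS, sample(3:10, 1), replace = TRUE), collapse = ""),
    character(1)))[seq_len(m)]
  n <- 16381
  observed <- m - length(unique(hash_key(keys, n)))
  expected <- m - n * (1 - (1 - 1 / n)^m)
  sigma <- sqrt(expected)  # Poisson-scale spread of the collision count
  expect_lt(abs(observed - expected), 3 * max(sigma, 1))
})

test_that("fingerprints are invariant to rigid motion and atom order", {
  for (seed in 1:5) {
    st <- make_structure(60, seed = seed)
    fp <- fingerprint(st)
    fp_rot <- fingerprint(rigid_transform(st, seed))
    expect_identical(fp$on_bits, fp_rot$on_bits)
    st_shuf <- st
    set.seed(seed)
    st_shuf$atoms <- st$atoms[sample(nrow(st$atoms)), ]
    fp_shuf <- fingerprint(st_shuf)
    expect_identical(fp$on_bits, fp_shuf$on_bits)
  }
})

test_that("popcount is bounded by distinct keys and atoms swept", {
  st <- make_structure(100, seed = 9)
  fp <- fingerprint(st)
  expect_lte(length(fp$on_bits), length(fp$keys))
  expect_lte(length(fp$keys), nrow(st$atoms))
  expect_equal(fp$n_bits, 16381L)
})

test_that("jaccard satisfies identity, disjointness, symmetry and bounds", {
  f1 <- fingerprint(make_structure(50, seed = 1))
  f2 <- fingerprint(make_structure(50, seed = 2))
  expect_equal(jaccard(f1, f1), 1.0)
  expect_equal(jaccard(f1, f2), jaccard(f2, f1))
  expect_gte(jaccard(f1, f2), 0)
  expect_lte(jaccard(f1, f2), 1)
  fa <- f1; fa$on_bits <- c(1L, 2L)
  fb <- f1; fb$on_bits <- c(3L, 4L)
  expect_equal(jaccard(fa, fb), 0)
  fc <- f1; fc$n_bits <- 2048L
  expect_error(jaccard(f1, fc), "n_bits")
  fe <- f1; fe$on_bits <- integer(); fe$keys <- character()
  expect_error(jaccard(fe, fe), "empty")
})

test_that("similarity matrix is symmetric with unit diagonal and ranks the top pair", {
  fps <- lapply(1:5, function(i)
    fingerprint(make_structure(40, seed = i,
                               structure_id = paste0("S", i)),
                n_bits = 512))
  m <- similarity_matrix(fps)
  expect_equal(diag(m), setNames(rep(1, 5), rownames(m)))
  expect_identical(m, t(m))
  # brute-force top pair over all 10 pairs
  best <- c(NA, NA); best_s <- -1
  for (i in 1:4) for (j in (i + 1):5) {
    s <- jaccard(fps[[i]], fps[[j]])
    if (s > best_s) { best_s <- s; best <- c(i, j) }
  }
  top <- closest_pairs(m, 1)
  expect_equal(sort(c(top$target, top$partner)),
               sort(rownames(m)[best]))
  expect_equal(top$similarity, best_s)
})

test_that("fingerprint files round-trip through the plain-text format", {
  fp <- fingerprint(make_structure(30, seed = 3))
  path <- tempfile(fileext = ".fp")
  write_fingerprint(fp, path)
  rt <- read_fingerprint(path)
  expect_equal(rt$structure_id, fp$structure_id)
  expect_equal(rt$n_bits, fp$n_bits)
  expect_equal(rt$on_bits, fp$on_bits)
  unlink(path)
})
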