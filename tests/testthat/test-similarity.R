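test_that("layer weights match direct evaluation and decrease monotonically", {
  expect_equal(layer_weight(1), 7 / 6)
  expect_equal(layer_weight(1), (2 / 6) * (1 / exp(0) + 5 / 2))
  expect_equal(layer_weight(6), (2 / 6) * (6 / exp(5) + 5 / 12))
  expect_equal(layer_weight(6), 0.15236, tolerance = 1e-4)
  w <- layer_weight(1:6)
  expect_true(all(diff(w) < 0))
  expect_error(layer_weight(0), "lambda")
})

test_that("Soergel layer distance matches hand evaluation and is bounded", {
  expect_equal(soergel_layer(c(2, 1), c(1, 1)), 0.25)
  expect_equal(soergel_layer(c(3, 0, 1), c(3, 0, 1)), 0)
  expect_equal(soergel_layer(c(1, 0, 0), c(0, 1, 0)), 1)
  set.seed(42)
  for (i in 1:50) {
    a <- rpois(8, 1)
    b <- rpois(8, 1)
    if (all(a == 0) && all(b == 0)) next
    d <- soergel_layer(a, b)
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_equal(d, soergel_layer(b, a))
  }
  expect_error(soergel_layer(c(1, 2), c(1, 2, 3)), "width")
})

test_that("Hamming layer distance is the absolute count difference", {
  expect_equal(hamming_layer(c(2, 1), c(1, 3)), 3)
  expect_equal(hamming_layer(c(5, 5), c(5, 5)), 0)
  set.seed(1)
  for (i in 1:25) {
    a <- rpois(6, 2); b <- rpois(6, 2)
    expect_equal(hamming_layer(a, b), hamming_layer(b, a))
  }
})

test_that("total distance is zero at identity and composes layer terms", {
  mol <- parse_smiles("COc1ccccc1")[[1]]
  fp <- atom_fingerprint(mol, 2)
  s <- total_distance(fp, fp)
  expect_equal(s$total, 0)
  expect_true(s$exact_prefix_ok)

  # identical layers 0-2 and 4-5; layer 3 differs by one count swap giving
  # soergel 0.25 and hamming 1 under hand-set vectors
  fa <- fp_from_key("C.3=1|O.3=1|C.ar=2|C.3=2;C.ar=1|PAD=1|PAD=1")
  fb <- fp_from_key("C.3=1|O.3=1|C.ar=2|C.3=1;C.ar=1|PAD=1|PAD=1")
  # layer 3 (lambda = 4): a = (2,1), b = (1,1) over {C.3, C.ar}
  s2 <- total_distance(fa, fb)
  expect_true(s2$exact_prefix_ok)
  expect_equal(s2$per_layer_soergel[4], 0.25)
  expect_equal(s2$per_layer_hamming[4], 1L)
  expect_equal(s2$total, layer_weight(4) * 0.25 * 1)
  expect_equal(s2$total, 0.0687, tolerance = 1e-3)
  # identical prefix layers contribute nothing
  expect_equal(sum(s2$per_layer_soergel[1:3]), 0)
})

test_that("similarity decision combines the prefix filter and threshold", {
  fa <- fp_from_key("C.3=1|O.3=1|C.ar=2|PAD=1|PAD=1|PAD=1")
  fb <- fp_from_key("C.3=1|N.3=1|C.ar=2|PAD=1|PAD=1|PAD=1")
  expect_true(is_similar(fa, fa))
  expect_false(is_similar(fa, fb))   # layer-1 mismatch, regardless of total
  # inclusive threshold: craft a pair whose total equals the threshold
  fc <- fp_from_key("C.3=1|O.3=1|C.ar=2|C.3=2;C.ar=1|PAD=1|PAD=1")
  fd <- fp_from_key("C.3=1|O.3=1|C.ar=2|C.3=1;C.ar=1|PAD=1|PAD=1")
  tot <- total_distance(fc, fd)$total
  p_eq <- similarity_params(threshold = tot)
  expect_true(is_similar(fc, fd, p_eq))
})

test_that("similarity equals a naive term-by-term oracle, exhaustively", {
  # all fingerprints over a 3-type alphabet with counts <= 2 and 3 layers
  ab <- atom_type_alphabet()
  cols <- c("C.3", "O.3", "PAD")
  rows <- expand.grid(a = 0:2, b = 0:2, c = 0:2)
  rows <- rows[rowSums(rows) > 0, ]
  make_fp <- function(r1, r2, r3) {
    m <- matrix(0L, nrow = 3, ncol = length(ab$types),
                dimnames = list(paste0("L", 0:2), ab$types))
    m[1, cols] <- as.integer(rows[r1, ])
    m[2, cols] <- as.integer(rows[r2, ])
    m[3, cols] <- as.integer(rows[r3, ])
    structure(m, class = "fingerprint", alphabet_version = ab$version)
  }
  set.seed(99)
  idx <- matrix(sample(nrow(rows), 6 * 120, replace = TRUE), ncol = 6)
  params <- similarity_params(exact_depth = 1, threshold = 1.0, n_layers = 3)
  for (i in seq_len(nrow(idx))) {
    fa <- make_fp(idx[i, 1], idx[i, 2], idx[i, 3])
    fb <- make_fp(idx[i, 4], idx[i, 5], idx[i, 6])
    expect_identical(
      is_similar(fa, fb, params),
      naive_is_similar(unclass(fa), unclass(fb), 1, 1.0),
      label = paste("pair", i))
  }
})

test_that("total distance is symmetric and nonnegative on real fingerprints", {
  mols <- parse_smiles(c("COc1ccccc1", "CN1CCCCC1", "NCCCC(=O)O"))
  fps <- unlist(lapply(mols, molecule_fingerprints), recursive = FALSE)
  set.seed(3)
  pick <- matrix(sample(length(fps), 40, replace = TRUE), ncol = 2)
  for (i in seq_len(nrow(pick))) {
    a <- fps[[pick[i, 1]]]; b <- fps[[pick[i, 2]]]
    sab <- total_distance(a, b)$total
    expect_gte(sab, 0)
    expect_equal(sab, total_distance(b, a)$total)
  }
})
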