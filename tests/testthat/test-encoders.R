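test_that("influence vectors realize each polynomial family", {
  expect_equal(unclass(influence_vector(influence_spec("constant", c1 = 5), 2)),
               setNames(rep(5, 5), -2:2))
  expect_equal(unclass(influence_vector(
    influence_spec("quadratic", a2 = 1, b2 = 0), 2)),
    setNames(c(4, 1, 0, 1, 4), -2:2))
  # benchmark-tuned quadratic coefficients, frozen by direct evaluation
  expect_equal(unname(unclass(influence_vector(
    influence_spec("quadratic", a2 = -2.7, b2 = 67.1), 2))),
    c(56.3, 64.4, 67.1, 64.4, 56.3))
  expect_equal(unname(unclass(influence_vector(
    influence_spec("sqrt", a1 = 1, b1 = 0), 2))),
    c(sqrt(2), 1, 0, 1, sqrt(2)))
})

test_that("influence vectors match per-offset evaluation and are even", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(1:5, 1)
    k <- seq(-n, n)
    a <- runif(1, -10, 10)
    b <- runif(1, -100, 100)
    cc <- runif(1, -100, 100)
    v1 <- unname(unclass(influence_vector(influence_spec("constant", c1 = cc), n)))
    v2 <- unname(unclass(influence_vector(influence_spec("sqrt", a1 = a, b1 = b), n)))
    v3 <- unname(unclass(influence_vector(influence_spec("quadratic", a2 = a, b2 = b), n)))
    expect_equal(v1, rep(cc, 2 * n + 1))
    expect_equal(v2, a * sqrt(abs(k)) + b)
    expect_equal(v3, a * k^2 + b)
    # even-function requirement
    expect_equal(v2, rev(v2))
    expect_equal(v3, rev(v3))
  }
})

test_that("window encoding is the influence-by-property elementwise product", {
  tab <- single_property_table(c(A = 1, K = 2))
  iv1 <- influence_vector(influence_spec("constant", c1 = 1), 1)
  expect_equal(unname(encode_window("AKA", tab, iv1)), c(1, 2, 1))
  ivq <- influence_vector(influence_spec("quadratic", a2 = 1, b2 = 0), 1)
  expect_equal(unname(encode_window("AKA", tab, ivq)), c(1, 0, 1))
  # padding neutrality: X contributes zero whatever the influence
  expect_equal(unname(encode_window("XKA", tab, iv1)), c(0, 2, 1))
})

test_that("window encoding is linear in the influence vector", {
  tab <- toy_property_table()
  set.seed(11)
  w <- random_window(3)
  iv <- influence_vector(influence_spec("sqrt", a1 = 2, b1 = 1), 3)
  scaled <- iv
  scaled[] <- 2.5 * unclass(iv)
  expect_equal(unname(encode_window(w, tab, scaled)),
               2.5 * unname(encode_window(w, tab, iv)))
})

test_that("encoding layout is property-major with P x (2n+1) columns", {
  tab <- toy_property_table()
  iv <- influence_vector(influence_spec("constant", c1 = 1), 2)
  X <- encode_windows(c("AAKAA", "CCKCC"), tab, iv)
  expect_equal(dim(X), c(2L, 2L * 5L))
  expect_equal(colnames(X)[1:5], paste0("p1@", -2:2))
  expect_equal(colnames(X)[6:10], paste0("p2@", -2:2))
  # sum reduction pools per property
  Xs <- encode_windows(c("AAKAA", "CCKCC"), tab, iv, reduce = "sum")
  expect_equal(dim(Xs), c(2L, 2L))
  expect_equal(unname(Xs[, "p1"]), unname(rowSums(X[, 1:5])))
})

test_that("encoders reject mismatched influence length", {
  tab <- toy_property_table()
  iv <- influence_vector(influence_spec("constant", c1 = 1), 3)
  expect_error(encode_windows("AKA", tab, iv), "does not match")
})

test_that("binary encoding is one-hot and decodable", {
  X <- encode_binary("AKA")
  expect_equal(ncol(X), 60L)
  expect_equal(sum(X), 3)
  X <- encode_binary("XKA")
  expect_equal(sum(X), 2)
  # decode oracle: recover the original window from the hot positions
  set.seed(5)
  for (rep in 1:10) {
    w <- random_window(4, alphabet = c(AA_ALPHABET, "X"))
    X <- encode_binary(w)
    decoded <- vapply(seq_len(nchar(w)), function(j) {
      block <- X[1, ((j - 1) * 20 + 1):(j * 20)]
      if (sum(block) == 0) "X" else AA_ALPHABET[which(block == 1)]
    }, character(1))
    expect_equal(paste(decoded, collapse = ""), w)
  }
})

test_that("composition encoding matches brute-force counting and sums to 1", {
  X <- encode_aac("AAKAA")
  expect_equal(unname(X[, "A"]), 0.8)
  expect_equal(unname(X[, "K"]), 0.2)
  expect_equal(sum(X), 1)
  set.seed(6)
  wins <- replicate(100, random_window(5, c(AA_ALPHABET, "X")))
  X <- encode_aac(wins)
  expect_equal(unname(rowSums(X)), rep(1, 100))
  for (i in c(1, 50, 100)) {
    ch <- strsplit(wins[i], "")[[1]]
    ch <- ch[ch != "X"]
    expect_equal(unname(X[i, "K"]), sum(ch == "K") / length(ch))
  }
  # grouped variant partitions the alphabet
  Xg <- encode_aac(wins, grouped = TRUE)
  expect_equal(ncol(Xg), 4L)
  expect_equal(unname(rowSums(Xg)), rep(1, 100))
  expect_error(encode_aac("XXX"), "only of 'X'")
})

test_that("mean physico-chemical encoding equals the brute-force mean", {
  tab <- single_property_table(c(A = 1, K = 2))
  expect_equal(unname(encode_physchem_mean("AKA", tab)[1, 1]), 4 / 3)
  expect_equal(unname(encode_physchem_mean("KKK", tab)[1, 1]), 2)
  tab2 <- toy_property_table()
  set.seed(8)
  wins <- replicate(20, random_window(4, c(AA_ALPHABET, "X")))
  X <- encode_physchem_mean(wins, tab2)
  for (i in c(3, 17)) {
    ch <- strsplit(wins[i], "")[[1]]
    keep <- ch != "X"
    vals <- unclass(tab2)[1, match(ch[keep], AA_ALPHABET)]
    expect_equal(unname(X[i, "p1"]), mean(vals))
  }
})

test_that("property tables standardize, round-trip, and handle X as zero", {
  tab <- default_property_table()
  expect_equal(dim(tab), c(13L, 20L))
  expect_true(isTRUE(attr(tab, "standardized")))
  v <- unclass(tab)
  expect_equal(unname(rowMeans(v)), rep(0, 13))
  expect_equal(unname(apply(v, 1, sd)), rep(1, 13))

  raw <- default_property_table(standardize = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_property_table(raw, path)
  back <- read_property_table(path, standardize = FALSE)
  expect_equal(unclass(back), unclass(raw))

  expect_error(read_property_table(tempfile()), "not found")
  expect_error(default_property_table(ids = "NOPE000000"), "not found")
})
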