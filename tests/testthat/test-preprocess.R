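test_that("probe collapsing averages duplicated gene rows", {
  m <- matrix(c(1, 3, 3, 5), 2, 2, byrow = TRUE,
              dimnames = list(c("G1", "G1"), c("s1", "s2")))
  out <- collapseProbes(m)
  expect_equal(out, matrix(c(2, 4), 1, dimnames = list("G1", c("s1", "s2"))))

  u <- matrix(1:4, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_identical(collapseProbes(u), u)

  m3 <- matrix(c(0, 0, 3, 3, 6, 6), 3, 2, byrow = TRUE,
               dimnames = list(rep("G", 3), c("s1", "s2")))
  expect_equal(unname(collapseProbes(m3)), matrix(3, 1, 2))
})

test_that("ANOVA filter matches the classical one-way F test", {
  g <- c(s1 = "a", s2 = "a", s3 = "b", s4 = "b")
  # worked case: SSB = 4, SSW = 1, df (1, 2) -> F = 8, p ~ 0.1056
  m <- matrix(c(1, 2, 3, 4), 1, dimnames = list("lin", names(g)))
  out <- anovaFilter(m, g, alpha = 0.05)
  expect_equal(nrow(out), 0)                      # p = 0.1056 > 0.05
  out2 <- anovaFilter(m, g, alpha = 0.2)
  expect_equal(nrow(out2), 1)
  expect_equal(unname(attr(out2, "anova")[1, "F"]), 8)
  expect_equal(unname(attr(out2, "anova")[1, "p"]), 0.1055728, tolerance = 1e-6)

  # agreement with stats::oneway.test on random data
  set.seed(11)
  rm <- matrix(rnorm(40 * 8), 40, 8,
               dimnames = list(paste0("g", 1:40), paste0("s", 1:8)))
  g8 <- setNames(rep(c("x", "y"), each = 4), colnames(rm))
  filt <- anovaFilter(rm, g8, alpha = 0.5)
  pv <- attr(filt, "anova")[, "p"]
  for (gene in sample(rownames(filt), 5)) {
    ref <- stats::oneway.test(rm[gene, ] ~ g8, var.equal = TRUE)$p.value
    expect_equal(unname(pv[gene]), ref, tolerance = 1e-12)
  }
})

test_that("ANOVA filter handles degenerate genes and designs", {
  g <- c(s1 = "a", s2 = "a", s3 = "b", s4 = "b")
  m <- rbind(flat = rep(5, 4), ok = c(0, 0, 9, 9))
  colnames(m) <- names(g)
  expect_message(out <- anovaFilter(m, g, alpha = 0.05), "zero-variance")
  expect_identical(rownames(out), "ok")
  # one sample per group: no within degrees of freedom
  g1 <- setNames(letters[1:4], names(g))
  expect_error(anovaFilter(m, g1, alpha = 0.05), "degrees of freedom")
})

test_that("ANOVA retention is monotone in alpha and catches large shifts", {
  set.seed(21)
  m <- matrix(rnorm(100 * 6), 100, 6,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  g <- setNames(rep(c("a", "b"), each = 3), colnames(m))
  alphas <- c(0.01, 0.05, 0.2, 0.5, 0.999)
  kept <- vapply(alphas, function(a)
    nrow(suppressMessages(anovaFilter(m, g, a))), numeric(1))
  expect_true(all(diff(kept) >= 0))
  expect_equal(kept[length(kept)], 100)           # alpha ~ 1 keeps everything

  # 10-sigma group shift, 3 per group: essentially always retained
  hits <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    gene <- matrix(c(rnorm(3), rnorm(3, 10)), 1,
                   dimnames = list("shift", names(g)))
    nrow(suppressMessages(anovaFilter(gene, g, 0.05)))
  }, numeric(1))
  expect_gte(mean(hits), 0.99)
})

test_that("z-transformation standardizes rows and is scale invariant", {
  m <- matrix(c(1, 2, 3), 1, dimnames = list("g", paste0("s", 1:3)))
  expect_equal(unname(zTransform(m)), matrix(c(-1, 0, 1), 1))
  # idempotence
  z <- zTransform(m)
  expect_equal(zTransform(z), z, tolerance = 1e-12)
  # every row mean 0, sd 1
  set.seed(5)
  rm <- matrix(rnorm(50 * 7), 50, 7,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:7)))
  z2 <- zTransform(rm)
  expect_lt(max(abs(rowMeans(z2))), 1e-9)
  expect_lt(max(abs(apply(z2, 1, sd) - 1)), 1e-9)
  # location/scale invariance
  expect_equal(zTransform(3.7 * rm + 11), z2, tolerance = 1e-9)
  # zero-variance row must error
  expect_error(zTransform(rbind(rm, const = rep(2, 7))), "zero-variance")
})

test_that("network restriction keeps only fully measured edges", {
  g <- igraph::graph_from_literal(A - B, B - C)
  z <- matrix(0:3, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  r <- suppressMessages(restrictToMeasured(g, z))
  expect_setequal(igraph::V(r)$name, c("A", "B"))
  expect_equal(igraph::ecount(r), 1)
  # identity when everything is measured
  z3 <- matrix(rnorm(6), 3, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  r3 <- restrictToMeasured(g, z3)
  expect_equal(igraph::ecount(r3), 2)
  # nothing measured -> namespace advice
  zx <- matrix(0:1, 1, dimnames = list("X", c("s1", "s2")))
  expect_error(restrictToMeasured(g, zx), "namespace")
})
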