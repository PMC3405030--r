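test_that("condition systems encode WSS differences", {
  V <- matrix(c(0, 0, 10, 10), 1, dimnames = list("M1", paste0("s", 1:4)))
  cs <- buildConditions(V, c(1L, 1L, 2L, 2L), list(c(1L, 2L, 1L, 2L)))
  expect_equal(unname(cs@A), matrix(100, 1, 1))
  # a misplaced copy of the target among the alternatives is rejected
  expect_error(buildConditions(V, c(1L, 1L, 2L, 2L),
                               list(c(1L, 1L, 2L, 2L))), "target")
  # margins are linear: x = (1,1) gives column sums of A
  V2 <- rbind(M1 = c(0, 0, 10, 10), M2 = c(5, 0, 5, 0))
  colnames(V2) <- paste0("s", 1:4)
  cs2 <- buildConditions(V2, c(1L, 1L, 2L, 2L),
                         list(c(1L, 2L, 1L, 2L), c(1L, 2L, 2L, 1L)))
  ev <- evaluateSelection(c(1, 1), cs2)
  expect_equal(unname(ev$margins), unname(colSums(cs2@A)))
})

test_that("selection evaluation computes margins, feasibility, power", {
  ev <- evaluateSelection(1, csFromA(matrix(100, 1, 1)))
  expect_equal(unname(ev$margins), 100)
  expect_true(ev$feasible)
  expect_equal(ev$power, 0)

  ev2 <- evaluateSelection(1, csFromA(matrix(-2, 1, 1)))
  expect_false(ev2$feasible)
  expect_equal(ev2$power, 2)

  A <- rbind(c(5, -1), c(-1, 5))
  ev3 <- evaluateSelection(c(1, 1), csFromA(A))
  expect_equal(unname(ev3$margins), c(4, 4))
  expect_equal(ev3$power, 0)
})

test_that("exact solver returns the minimum-cardinality feasible set", {
  A <- rbind(c(5, -1), c(-1, 5), c(-3, -3))
  res <- solveExact(csFromA(A))
  expect_identical(res@selected, c(1L, 2L))
  expect_true(res@feasible)

  # an all-positive row wins as a singleton, lowest index on ties
  B <- rbind(c(1, -5), c(2, 3), c(2, 3))
  resB <- solveExact(csFromA(B))
  expect_identical(resB@selected, 2L)

  # all-negative contributions are infeasible
  resC <- solveExact(csFromA(matrix(-1, 2, 3)))
  expect_false(resC@feasible)
  expect_length(resC@selected, 0)

  expect_error(solveExact(csFromA(matrix(1, 25, 2))), "maxK")
})

test_that("ranking scores are negated row sums with stable ties", {
  A <- rbind(c(5, -1), c(-1, 5), c(-3, -3))
  rk <- rankModules(csFromA(A))
  expect_equal(rk$scores, c(-4, -4, 6))
  expect_identical(rk$ordering, c(1L, 2L, 3L))
  # single module: trivially first
  expect_identical(rankModules(csFromA(matrix(-9, 1, 1)))$ordering, 1L)
  # identical rows preserve original order
  rk2 <- rankModules(csFromA(rbind(c(2, 2), c(2, 2))))
  expect_identical(rk2$ordering, c(1L, 2L))
})

test_that("greedy prefix selection follows the average-power trace", {
  A <- rbind(c(5, -1), c(-1, 5), c(-3, -3))
  res <- greedySelect(csFromA(A))
  expect_equal(res@powerTrace, c(1, 0, 0))
  expect_identical(res@nStar, 2L)                 # smallest minimizing prefix
  expect_identical(res@selected, c(1L, 2L))
  expect_true(res@feasible)
  expect_identical(res@selected, solveExact(csFromA(A))@selected)

  resPos <- greedySelect(csFromA(matrix(c(3, 2), 1, 2)))
  expect_identical(resPos@nStar, 1L)
  expect_equal(resPos@powerTrace[1], 0)

  resNeg <- greedySelect(csFromA(matrix(-4, 1, 1)))
  expect_identical(resNeg@nStar, 1L)
  expect_false(resNeg@feasible)
})

test_that("greedy is never smaller than the exact optimum when feasible", {
  feasible <- 0; ratio <- c()
  for (i in 1:40) {
    set.seed(200 + i)
    K <- sample(2:8, 1); R <- sample(2:12, 1)
    A <- matrix(rnorm(K * R, mean = 0.3), K, R)
    cs <- csFromA(A)
    ex <- solveExact(cs); gr <- greedySelect(cs)
    if (gr@feasible) {
      feasible <- feasible + 1
      expect_true(ex@feasible)                    # greedy feasible => exact is
      expect_gte(length(gr@selected), length(ex@selected))
      ratio <- c(ratio, length(gr@selected) / length(ex@selected))
    }
  }
  expect_gt(feasible, 5)                          # the regime is non-trivial
})

test_that("feasibility certifies target optimality in the selected subspace", {
  set.seed(77)
  for (i in 1:10) {
    V <- matrix(rnorm(4 * 6), 4, 6,
                dimnames = list(paste0("M", 1:4), paste0("s", 1:6)))
    target <- canonicalPartition(sample(1:2, 6, replace = TRUE))
    if (max(target) < 2) next
    alts <- Filter(function(p) partitionKey(p) != partitionKey(target),
                   enumeratePartitions(6, max(target)))
    cs <- buildConditions(V, target, alts)
    x <- rbinom(4, 1, 0.6); if (sum(x) == 0) x[1] <- 1
    ev <- evaluateSelection(x, cs)
    Wtarget <- bruteSubspaceSSE(V, which(x == 1), target)
    Wall <- vapply(alts, function(p)
      bruteSubspaceSSE(V, which(x == 1), p), numeric(1))
    expect_equal(ev$feasible, all(Wall >= Wtarget - 1e-9))
  }
})

test_that("selectModules picks mode automatically and threads metadata", {
  set.seed(88)
  V <- matrix(rnorm(3 * 6), 3, 6,
              dimnames = list(paste0("M", 1:3), paste0("s", 1:6)))
  labs <- setNames(rep(c("a", "b", "c"), each = 2), colnames(V))
  res <- selectModules(V, labs)
  expect_identical(res@info$mode, "exhaustive")   # S(6,3) = 90
  expect_equal(res@info$nAlternatives, 89)
  res2 <- selectModules(V, labs, mode = "neighborhood", d = 1)
  expect_identical(res2@info$mode, "neighborhood")
  expect_error(selectModules(V, setNames(rep("a", 6), colnames(V))),
               "two phenotype groups")
})
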