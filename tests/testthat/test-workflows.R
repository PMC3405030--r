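arrestDesign <- function(seed, delta = 2) {
  studyDesign(conditions = c("control", "MMS"),
              responsivePlan = list(P1 = c("control:G2M", "MMS:G2M"),
                                    P2 = c("MMS:S", "MMS:G2M"),
                                    P3 = "MMS:G2M"),
              delta = delta, seed = seed)
}

test_that("modules are assigned to the phase of maximal mean activity", {
  V <- rbind(M1 = c(0.1, 0.1, 2.0, 2.0, 0.3, 0.3),
             M2 = c(1, 1, 1, 1, 1, 1))
  colnames(V) <- paste0("s", 1:6)
  ph <- setNames(rep(c("G1", "S", "G2M"), each = 2), colnames(V))
  pa <- assignPhases(V, ph)
  expect_identical(pa$phase[pa$module == "M1"], "S")
  # all-equal means tie to the first phase, flagged
  expect_identical(pa$phase[pa$module == "M2"], "G1")
  expect_true(pa$tied[pa$module == "M2"])
  expect_false(pa$tied[pa$module == "M1"])
  # replicate order cannot matter
  perm <- c(2, 1, 4, 3, 6, 5)
  pa2 <- assignPhases(V[, perm], ph[perm])
  expect_identical(pa2$phase, pa$phase)
  # single replicate per phase: means equal raw values
  V1 <- V[, c(1, 3, 5)]
  pa3 <- assignPhases(V1, ph[c(1, 3, 5)])
  expect_equal(unname(attr(pa3, "phaseMeans")["M1", ]),
               unname(V["M1", c(1, 3, 5)]))
})

test_that("group-wise selection recovers planted modules and matches the
           whole-dataset run on a single-condition study", {
  d <- studyDesign(conditions = "wt", nResponsive = 2L, delta = 3,
                   seed = 19L)
  st <- makeStudy(d)
  run <- runStudySelection(st)
  res <- identifyGroupModules(run$z, run$filtered, st$labels, "wt")
  expect_true(res@feasible)
  sel_planted <- unique(mapToPlanted(
    moduleMembers(run$filtered)[res@selected],
    moduleMembers(st$truth$modules)))
  expect_setequal(sel_planted, names(st$truth$plan))

  # the single condition IS the whole dataset: results must agree
  direct <- selectModules(run$responsive, st$labels[colnames(run$z)])
  expect_identical(res@selected, direct@selected)
  expect_equal(res@margins, direct@margins)

  # fewer than two phases is a contract violation
  one_phase <- st$labels
  one_phase[] <- "wt:G1"
  expect_error(identifyGroupModules(run$z, run$filtered, one_phase, "wt"),
               "two phases")
  expect_error(identifyGroupModules(run$z, run$filtered, st$labels, "nope"),
               "no sample")
})

test_that("transition selection flags the module shifted only under
           stimulus in the later phase", {
  st <- makeStudy(arrestDesign(seed = 23L, delta = 3))
  run <- runStudySelection(st)
  res <- identifyTransitionModules(run$z, run$filtered, st$labels,
                                   stimulus = "MMS", phaseA = "S",
                                   phaseB = "G2M")
  expect_true(res@feasible)
  sel_planted <- mapToPlanted(moduleMembers(run$filtered)[res@selected],
                              moduleMembers(st$truth$modules))
  expect_true("P3" %in% sel_planted)
  expect_identical(res@info$transition$from, "S")

  # a missing condition x phase cell aborts up front
  labs <- st$labels[!(st$labels == "MMS:G2M")]
  expect_error(identifyTransitionModules(run$z[, names(labs)],
                                         run$filtered, labs,
                                         stimulus = "MMS", phaseA = "S",
                                         phaseB = "G2M"),
               "empty condition")
})

test_that("null transitions (delta = 0) do not crash and rarely attribute
           the designated module", {
  hits <- vapply(1:25, function(s) {
    st <- makeStudy(arrestDesign(seed = 400L + s, delta = 0))
    run <- runStudySelection(st)
    res <- identifyTransitionModules(run$z, run$filtered, st$labels,
                                     stimulus = "MMS", phaseA = "S",
                                     phaseB = "G2M")
    expect_s4_class(res, "SelectionResult")
    sel_planted <- mapToPlanted(moduleMembers(run$filtered)[res@selected],
                                moduleMembers(st$truth$modules))
    res@feasible && "P3" %in% sel_planted
  }, logical(1))
  expect_lt(mean(hits), 0.2)
})

test_that("hypergeometric enrichment matches closed-form tail cases", {
  bg <- paste0("g", 1:10)
  ms <- new("ModuleSet", modules = list(M1 = bg[1:3]))
  sets <- new("GeneSets", setIds = c("hit", "brush", "ghost"),
              descriptions = c("", "", ""),
              members = list(bg[1:5], bg[3:5], c("x1", "x2")))
  tab <- hypergeomEnrichment(ms, sets, bg)
  expect_equal(tab$p[tab$term == "hit"], choose(5, 3) / choose(10, 3),
               tolerance = 1e-12)                  # 10/120
  # overlap 1 with a 3-member term: P(X >= 1) = 1 - C(7,3)/C(10,3)
  expect_equal(tab$p[tab$term == "brush"], 1 - choose(7, 3) / choose(10, 3),
               tolerance = 1e-12)
  # term disjoint from the background: degenerate, p = 1
  expect_true(tab$degenerate[tab$term == "ghost"])
  expect_equal(tab$p[tab$term == "ghost"], 1)
  # zero overlap gives p = 1 (upper tail from 0)
  ms0 <- new("ModuleSet", modules = list(M = bg[6:7]))
  sets0 <- new("GeneSets", setIds = "t", descriptions = "",
               members = list(bg[1:3]))
  expect_equal(hypergeomEnrichment(ms0, sets0, bg)$p, 1)
  # sorted by p, BH option appends adjusted values
  expect_false(is.unsorted(tab$p))
  tabBH <- hypergeomEnrichment(ms, sets, bg, adjust = "BH")
  expect_equal(tabBH$p_adj, p.adjust(tabBH$p, "BH"))
  # module member outside the background is a contract violation
  expect_error(hypergeomEnrichment(
    new("ModuleSet", modules = list(M = "alien")), sets, bg), "background")
})

test_that("external validation is label-permutation invariant and handles
           the singleton-cluster limit", {
  set.seed(61)
  z <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  z[1:4, 1:2] <- z[1:4, 1:2] + 5
  ms <- new("ModuleSet", modules = list(M1 = paste0("g", 1:4),
                                        M2 = paste0("g", 5:8)))
  ph <- setNames(rep(c("G1", "S", "G2M"), each = 2), colnames(z))
  rep1 <- validateExternal(z, ms, ph, C = 3)
  relab <- setNames(c(G1 = "x", S = "y", G2M = "z")[ph], names(ph))
  rep2 <- validateExternal(z, ms, relab, C = 3)
  expect_equal(rep1@ari, rep2@ari)
  # C = number of samples: every sample its own cluster, ARI still defined
  rep3 <- validateExternal(z, ms, ph, C = 6)
  expect_length(unique(rep3@clusters), 6)
  expect_true(is.finite(rep3@ari))
  # modules losing too many members are dropped, with a warning
  z2 <- z[paste0("g", c(1:4, 9:10)), ]
  expect_warning(rep4 <- validateExternal(z2, ms, ph, C = 3), "missing")
  expect_identical(rep4@modulesUsed, "M1")
})
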