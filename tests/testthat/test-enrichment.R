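test_that("glog transform has the right limits and stabilizes variance", {
  v <- matrix(c(1, 2, 4, 8), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  om <- makeOmics(v, groups = c("AF", "sham"))
  # c = 0 reduces to plain log2
  expect_equal(omicsValues(vstTransform(om, c = 0, calibrate = FALSE)),
               log2(v), tolerance = 1e-12)
  # closed form at zero
  om0 <- makeOmics(matrix(c(0, 4), 1, 2), groups = c("AF", "sham"))
  g <- omicsValues(vstTransform(om0, c = 2, calibrate = FALSE))
  expect_equal(g[1, 1], log2(2 / 2), tolerance = 1e-12)

  # heteroscedastic synthetic input: variance ~ mean^2 at low intensity
  set.seed(50)
  mu <- exp(seq(log(5), log(5000), length.out = 200))
  raw <- vapply(1:6, function(j) mu * exp(rnorm(200, 0, 0.1)) +
                  rnorm(200, 0, 5), numeric(200))
  raw <- pmax(raw, 0.01)
  dimnames(raw) <- list(sprintf("f%03d", 1:200), sprintf("s%d", 1:6))
  om2 <- makeOmics(raw)
  slopeOf <- function(m) {
    rm <- rowMeans(m); rs <- apply(m, 1, sd)
    unname(coef(lm(rs ~ rm))[2])
  }
  before <- slopeOf(log2(raw))
  after <- slopeOf(omicsValues(vstTransform(om2)))
  expect_lt(abs(after), abs(before))
})

test_that("id harmonization collapses collisions and drops the unmapped", {
  v <- matrix(as.numeric(1:12), 4, 3,
              dimnames = list(c("g1", "g2", "g3", "g4"),
                              c("s1", "s2", "s3")))
  om <- makeOmics(v, groups = c("AF", "AF", "sham"))
  idmap <- data.frame(source = c("g1", "g2", "g3"),
                      target = c("H1", "H1", "H2"))
  expect_message(out <- harmonizeIds(list(om), idmap)[[1]], "1 unmapped")
  expect_setequal(rownames(out), c("H1", "H2"))
  expect_equal(omicsValues(out)["H1", ],
               apply(v[c("g1", "g2"), ], 2, median), tolerance = 1e-12)
  expect_equal(unname(omicsValues(out)["H2", ]), unname(v["g3", ]))

  # identity map leaves the matrix unchanged
  idm <- data.frame(source = rownames(v), target = rownames(v))
  same <- harmonizeIds(list(om), idm)[[1]]
  expect_equal(omicsValues(same)[rownames(v), ], v)

  # collision count arithmetic on a synthetic map
  set.seed(60)
  ids <- sprintf("g%02d", 1:40)
  vv <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(ids, paste0("s", 1:4)))
  om2 <- makeOmics(vv, groups = c("AF", "AF", "sham", "sham"))
  map <- data.frame(source = ids,
                    target = c(sprintf("H%02d", 1:30),
                               sprintf("H%02d", 1:10)))  # 10 collisions
  out2 <- harmonizeIds(list(om2), map)[[1]]
  expect_equal(nrow(out2), 40 - 10)
  expect_error(harmonizeIds(list(om2), data.frame(source = "zz",
                                                  target = "H1")),
               "covered")
  # max_abs keeps the entry of largest magnitude
  om3 <- makeOmics(matrix(c(1, -5, 2, 3), 2, 2,
                          dimnames = list(c("a", "b"), c("x", "y"))),
                   groups = c("AF", "sham"))
  m3 <- data.frame(source = c("a", "b"), target = c("H", "H"))
  out3 <- harmonizeIds(list(om3), m3, collapse = "max_abs")[[1]]
  expect_equal(unname(omicsValues(out3)["H", ]), c(-5, 3))
})

test_that("outlier detection flags exactly a planted extreme sample", {
  set.seed(70)
  v <- matrix(rnorm(100 * 6, 10), 100, 6,
              dimnames = list(sprintf("f%03d", 1:100), sprintf("s%d", 1:6)))
  om <- makeOmics(v)
  expect_length(detectOutlierSamples(list(om), thresholdMad = 5), 0)
  expect_length(detectOutlierSamples(list(om), thresholdMad = Inf), 0)

  v2 <- v; v2[, 2] <- v[, 2] * 10
  om2 <- makeOmics(v2)
  # flagging s2 would leave the AF group with 2 samples: allowed
  flagged <- detectOutlierSamples(list(om2), thresholdMad = 5)
  expect_identical(as.character(flagged), "s2")
})

test_that("per-gene t statistics match the direct formula and mark degeneracies", {
  set.seed(80)
  v <- matrix(rnorm(12), 2, 6)
  om <- makeOmics(v)
  st <- geneTStats(om)
  o <- oracleT(v[1, 1:3], v[1, 4:6])
  expect_equal(st$t[1], o$t, tolerance = 1e-12)

  # identical groups -> 0; zero-variance shift -> infinite sentinel
  v2 <- rbind(rep(c(1, 2, 3), 2), c(5, 5, 5, 3, 3, 3))
  st2 <- geneTStats(makeOmics(v2))
  expect_equal(st2$t[1], 0)
  expect_identical(st2$t[2], Inf)
  expect_identical(st2$status[2], "degenerate")

  v3 <- v; v3[1, c(1, 2)] <- NA
  st3 <- geneTStats(makeOmics(v3))
  expect_true(is.na(st3$t[1]))
  expect_identical(st3$status[1], "missing")
})

test_that("ranking applies the cross-omics missing-value policy", {
  t_tl <- c(gA = -2, gB = 0.5, gC = 3)
  t_el <- c(gA = 1, gD = -1)            # gB, gC ranked last here
  t_rna <- c(gA = 0.2, gE = 2, gF = -3) # gE, gF are RNA-only
  prof <- rankDatasets(list(TL = t_tl, EL = t_el, RNA = t_rna),
                       proteomicsTags = c("TL", "EL"))
  # gD (observed in EL only) is ranked_last in TL; observed genes rank above
  expect_identical(unname(prof$status$TL["gD"]), "ranked_last")
  expect_equal(prof$ranks$TL[c("gD", "gA", "gB", "gC")],
               c(gD = 1, gA = 2, gB = 3, gC = 4))
  # with no cross-dataset missingness the ranks are the plain mid-ranks
  profFull <- rankDatasets(list(TL = t_tl, EL = t_tl + 1),
                           proteomicsTags = c("TL", "EL"))
  expect_equal(profFull$ranks$TL[names(t_tl)],
               setNames(rank(t_tl), names(t_tl)))
  # gB/gC observed in TL only: ranked_last block at the bottom of EL
  expect_identical(unname(prof$status$EL[c("gB", "gC")]),
                   rep("ranked_last", 2))
  expect_equal(unname(prof$ranks$EL[c("gB", "gC")]), c(1.5, 1.5))
  expect_equal(unname(prof$ranks$EL[c("gD", "gA")]), c(3, 4))
  # RNA-only genes are excluded from proteomics rankings entirely
  expect_false(any(c("gE", "gF") %in% names(prof$ranks$TL)))
  expect_false(any(c("gE", "gF") %in% names(prof$ranks$EL)))
  # RNA ranks cover exactly the genes with transcript statistics
  expect_setequal(names(prof$ranks$RNA), c("gA", "gE", "gF"))
  # proteomics-only genes do not leak into the RNA ranking
  expect_false("gD" %in% names(prof$ranks$RNA))
})

test_that("category scores have the closed form, zero-sum and symmetry", {
  t1 <- setNames(seq_len(100) + 0.0, sprintf("g%03d", 1:100))
  prof <- rankDatasets(list(D = t1), proteomicsTags = "D")
  # whole universe scores exactly zero
  expect_equal(unname(categoryScores(prof, names(t1))), 0)
  # top-2 members of n = 100: (2/100) * (99.5 - 50.5) = 0.98
  top2 <- names(sort(t1, decreasing = TRUE))[1:2]
  expect_equal(unname(categoryScores(prof, top2)), 0.98, tolerance = 1e-12)
  # reversing the statistic flips the sign
  profRev <- rankDatasets(list(D = -t1), proteomicsTags = "D")
  expect_equal(unname(categoryScores(profRev, top2)), -0.98,
               tolerance = 1e-12)
})

test_that("one-dimensional MANOVA reduces to the normal-approximation Wilcoxon", {
  set.seed(90)
  t1 <- setNames(rnorm(40), sprintf("g%02d", 1:40))
  prof <- rankDatasets(list(D = t1), proteomicsTags = "D")
  mem <- sample(names(t1), 8)
  res <- manovaEnrichmentTest(prof, mem)
  r <- rank(t1)
  W <- sum(r[mem]); n <- 40; k <- 8
  zw <- (W - k * (n + 1) / 2) / sqrt(k * (n - k) * (n + 1) / 12)
  expect_equal(res$p, 2 * pnorm(-abs(zw)), tolerance = 1e-10)
})

test_that("MANOVA p agrees with a drawn-category permutation oracle", {
  set.seed(91)
  ids <- sprintf("h%03d", 1:100)
  t1 <- setNames(rnorm(100), ids); t2 <- setNames(rnorm(100), ids)
  prof <- rankDatasets(list(A = t1, B = t2), proteomicsTags = c("A", "B"))
  C <- atriomics:::.rankCorrelation(prof)
  oracleP <- function(mem, k, nDraw = 4000) {
    obs <- manovaEnrichmentTest(prof, mem, rankCor = C)$T2
    draws <- replicate(nDraw,
      manovaEnrichmentTest(prof, sample(ids, k), rankCor = C)$T2)
    mean(draws >= obs)
  }
  for (k in c(10, 20)) {
    mem <- sample(ids, k)
    pa <- manovaEnrichmentTest(prof, mem, rankCor = C)$p
    pp <- oracleP(mem, k)
    se <- sqrt(max(pp * (1 - pp), 1e-4) / 4000)
    expect_lt(abs(pa - pp), 2 * se + 0.01)
  }
  # tiny instance: the chi-square approximation is only as good as the
  # discreteness of 3-gene rank sums allows (~0.03-wide support steps)
  ids12 <- sprintf("j%02d", 1:12)
  s1 <- setNames(rnorm(12), ids12); s2 <- setNames(rnorm(12), ids12)
  prof12 <- rankDatasets(list(A = s1, B = s2), proteomicsTags = c("A", "B"))
  C12 <- atriomics:::.rankCorrelation(prof12)
  mem <- sample(ids12, 3)
  obs <- manovaEnrichmentTest(prof12, mem, rankCor = C12)
  draws <- replicate(4000,
    manovaEnrichmentTest(prof12, sample(ids12, 3), rankCor = C12)$T2)
  expect_lt(abs(obs$p - mean(draws >= obs$T2)), 0.08)
})

test_that("MANOVA is invariant to monotone transforms of the statistics", {
  set.seed(92)
  ids <- sprintf("g%02d", 1:50)
  t1 <- setNames(rnorm(50), ids); t2 <- setNames(rnorm(50), ids)
  mem <- sample(ids, 6)
  p1 <- manovaEnrichmentTest(
    rankDatasets(list(A = t1, B = t2), proteomicsTags = c("A", "B")), mem)$p
  p2 <- manovaEnrichmentTest(
    rankDatasets(list(A = tanh(t1), B = exp(t2)),
                 proteomicsTags = c("A", "B")), mem)$p
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("membership floor skips pathways with a reason", {
  t1 <- setNames(rnorm(20), sprintf("g%02d", 1:20))
  t2 <- setNames(rnorm(20), sprintf("g%02d", 1:20))
  prof <- rankDatasets(list(A = t1, B = t2), proteomicsTags = c("A", "B"))
  res <- manovaEnrichmentTest(prof, c("g01"), minPerSide = 2)
  expect_true(res$skipped)
  expect_match(res$reason, "fewer than 2")
})

test_that("q-values follow the BH step-up with its standard properties", {
  expect_equal(qValues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(qValues(1), 1)
  expect_equal(qValues(rep(1, 5)), rep(1, 5))
  expect_equal(qValues(0.37), 0.37)
  set.seed(93)
  p <- runif(50)
  q <- qValues(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(qValues(c(0.5, 1.2)), "0, 1")
})

test_that("confidence tiers match the 1 percent FDR policy", {
  tiers <- classifyTiers(c(0.5, 0.005, 1e-5))
  expect_identical(tiers$tier,
                   c("non_confident", "confident", "highly_confident"))
  expect_identical(tiers$significant, c(FALSE, TRUE, TRUE))
})

test_that("the integrated driver recovers a fully regulated planted pathway", {
  study <- simulateStudy(SimStudyConfig(seed = 94, n_features = 500,
                                        frac_regulated = 0.1,
                                        effect_log2 = 2,
                                        datasets = c("TL", "EL", "Mito")),
                         nPathways = 50)
  er <- enrichPathways(study$proteomics, study$transcripts, study$annotation)
  rt <- resultsTable(er)
  planted <- names(study$truth$regulated_pathways)
  expect_gt(length(planted), 0)
  hit <- rt$q[rt$pathway_id %in% planted]
  expect_true(all(hit < 0.01))
  expect_true(all(rt$score[rt$pathway_id %in% planted, "TL"] > 0))
})
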