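test_that("identical accuracies give zero F and p = 1 for every term", {
  tab <- expand.grid(tw = c(1, 5, 10), pai = c("SD", "LPA", "MVPA"),
                     replicate = 1:2)
  tab$accuracy <- 0.97
  res <- anovaTable(twoWayAnova(tab))
  expect_equal(res$F[1:3], c(0, 0, 0))
  expect_equal(res$p[1:3], c(1, 1, 1))
})

test_that("the 2x2 perfect-separation design decomposes as computed by hand", {
  tab <- data.frame(tw = rep(c("A1", "A2"), each = 4),
                    pai = rep(rep(c("B1", "B2"), each = 2), 2),
                    accuracy = c(1, 1, 1, 1, 0, 0, 0, 0))
  # definitional sums: means 1 and 0, grand 0.5 ->
  # SS_A = b*n*(0.25 + 0.25) = 2 = SS_total; all other sums are zero
  res <- anovaTable(twoWayAnova(tab))
  expect_equal(res$ss[res$term == "tw"], 2)
  expect_equal(res$ss[res$term == "pai"], 0)
  expect_equal(res$ss[res$term == "tw:pai"], 0)
  expect_equal(res$ss[res$term == "within"], 0)
  expect_equal(res$F[res$term == "tw"], Inf)
  expect_equal(res$p[res$term == "tw"], 0)
  expect_equal(res$F[res$term == "pai"], 0)
  expect_equal(res$p[res$term == "pai"], 1)
})

test_that("random balanced tables match the definitional oracle and aov", {
  set.seed(41)
  for (i in 1:20) {
    tab <- randomAccuracyTable(nRep = 2L + (i %% 3), effect = runif(1, 0, 2))
    res <- anovaTable(twoWayAnova(tab))
    oracle <- anovaOracle(tab)
    expect_equal(res$ss[1:4], c(oracle$ssA, oracle$ssB, oracle$ssAB,
                                oracle$ssW), tolerance = 1e-10)
    expect_equal(res$F[1], oracle$fA, tolerance = 1e-10)
    expect_equal(res$F[2], oracle$fB, tolerance = 1e-10)
    expect_equal(res$p[1], oracle$pA, tolerance = 1e-10)
    expect_equal(res$p[2], oracle$pB, tolerance = 1e-10)

    fit <- summary(aov(accuracy ~ factor(tw) * factor(pai), data = tab))[[1]]
    expect_equal(res$F[1:3], fit[["F value"]][1:3], tolerance = 1e-8)
    expect_equal(res$p[1:3], fit[["Pr(>F)"]][1:3], tolerance = 1e-8)
  }
})

test_that("sums of squares decompose the total on every balanced input", {
  set.seed(43)
  for (i in 1:20) {
    tab <- randomAccuracyTable(nRep = 3L)
    res <- anovaTable(twoWayAnova(tab))
    expect_equal(sum(res$ss[1:4]), res$ss[res$term == "total"],
                 tolerance = 1e-9)
  }
})

test_that("F statistics are invariant to adding a constant accuracy shift", {
  set.seed(47)
  tab <- randomAccuracyTable(nRep = 3L, effect = 1)
  res1 <- anovaTable(twoWayAnova(tab))
  tab$accuracy <- tab$accuracy + 0.3
  res2 <- anovaTable(twoWayAnova(tab))
  expect_equal(res1$F[1:3], res2$F[1:3], tolerance = 1e-9)
})

test_that("unbalanced designs are refused with the deficient cell named", {
  tab <- randomAccuracyTable(tws = c(1, 5), nRep = 3L)
  expect_error(twoWayAnova(tab[-1, ]), "tw=1, pai=SD")
  tab1 <- randomAccuracyTable(nRep = 1L)
  expect_error(twoWayAnova(tab1), ">= 2")
})

test_that("cell and margin summaries report mean (SD) with the n-1 denominator", {
  one <- data.frame(tw = 1, pai = "SD", accuracy = 0.9)
  s1 <- summarizeAccuracy(one)
  expect_true(is.na(s1$sd[1]))
  expect_equal(s1$mean[1], 0.9)

  two <- data.frame(tw = c(1, 1), pai = c("SD", "SD"),
                    accuracy = c(0.9, 1.1))
  s2 <- summarizeAccuracy(two)
  cell <- s2[!is.na(s2$tw) & !is.na(s2$pai), ]
  expect_equal(cell$mean[1], 1.0)
  expect_equal(cell$sd[1], sqrt(0.02), tolerance = 1e-12)  # 0.1414...

  same <- data.frame(tw = c(1, 1, 1), pai = "SD", accuracy = rep(0.8, 3))
  expect_equal(summarizeAccuracy(same)$sd[1], 0)
})

test_that("accuracy tables and ANOVA results round-trip through files", {
  tab <- randomAccuracyTable(nRep = 2L)
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, csv, row.names = FALSE)
  back <- readAccuracyTable(csv)
  expect_equal(back$accuracy, tab$accuracy)
  res <- twoWayAnova(back)
  js <- withr::local_tempfile(fileext = ".json")
  writeAnova(res, js)
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$table$F[1], anovaTable(res)$F[1])
})
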