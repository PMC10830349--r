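test_that("interannual change differences consecutive years and respects gaps", {
  panel <- abundance_panel(
    species = c(rep("a", 3), rep("b", 3), rep("c", 4)),
    year = c(2001:2003, 2001, 2002, 2004, 2001:2004),
    index = c(2.0, 2.3, 2.1, 2.0, NA, 2.4, 1.7, 1.7, 1.7, 1.7)
  )
  ch <- interannual_change(panel)
  expect_equal(ch$delta[ch$species == "a"], c(0.3, -0.2))
  # b: 2002 missing, 2004 not consecutive with 2001 -> no deltas at all
  expect_equal(sum(ch$species == "b"), 0L)
  expect_equal(ch$delta[ch$species == "c"], c(0, 0, 0))
  expect_equal(ch$year[ch$species == "a"], c(2001L, 2002L))
})

test_that("species with fewer than two observed years are dropped with a warning", {
  panel <- abundance_panel(c("a", "a", "b"), c(2001, 2002, 2001), c(1, 2, 3))
  expect_warning(ch <- interannual_change(panel), "b")
  expect_setequal(unique(ch$species), "a")
})

test_that("asynchrony maps correlation 1, 0, -1 to M = 0, 0.5, 1", {
  deltas <- list(
    i = c(1, 2, 3, 1, -1, 1, -1),
    j = c(2, 4, 6, 2, -2, 2, -2),   # perfectly synchronous with i
    k = c(3, 2, 1, -1, 1, -1, 1)    # reversed on the first three -> use pair below
  )
  ch <- rbind(
    data.frame(species = "i", year = 1:3, delta = c(1, 2, 3)),
    data.frame(species = "j", year = 1:3, delta = c(2, 4, 6)),
    data.frame(species = "k", year = 1:3, delta = c(3, 2, 1)),
    data.frame(species = "l", year = 1:4, delta = c(1, -1, 1, -1)),
    data.frame(species = "m", year = 1:4, delta = c(1, 1, -1, -1))
  )
  asy <- suppressMessages(asynchrony_matrix(ch, min_overlap = 3L))
  expect_equal(asy$M["i", "j"], 0)
  expect_equal(asy$M["i", "k"], 1)
  expect_equal(asy$M["l", "m"], 0.5)  # hand-computed Pearson r = 0
  expect_equal(diag(asy$M), setNames(rep(0, 5), rownames(asy$M)))
})

test_that("pairs below the overlap threshold or with zero variance are undefined", {
  ch <- rbind(
    data.frame(species = "a", year = 1:6, delta = rnorm(6)),
    data.frame(species = "b", year = 1:6, delta = rnorm(6)),
    data.frame(species = "c", year = 1:4, delta = rnorm(4)),   # only 4 shared
    data.frame(species = "d", year = 1:6, delta = rep(0.5, 6)) # zero variance
  )
  asy <- suppressMessages(asynchrony_matrix(ch, min_overlap = 5L))
  expect_false(is.na(asy$M["a", "b"]))
  expect_true(is.na(asy$M["a", "c"]))
  expect_true(is.na(asy$M["a", "d"]))
  expect_equal(asy$n_overlap["a", "c"], 4L)
})

test_that("asynchrony matches the double-loop Pearson oracle on gappy panels", {
  set.seed(401)
  for (rep_i in 1:3) {
    panel <- abundance_panel(
      species = rep(sprintf("sp%02d", 1:10), each = 15),
      year = rep(2001:2015, times = 10),
      index = rnorm(150, mean = 2, sd = 0.4)
    )
    drop <- sample.int(nrow(panel), 25)
    panel <- panel[-drop, ]
    ch <- interannual_change(panel)
    asy <- suppressMessages(asynchrony_matrix(ch, min_overlap = 5L))
    expect_equal(asy$M, oracle_asynchrony(ch, 5L), tolerance = 1e-12)
  }
})

test_that("M is invariant to index shifts and positive delta scaling, flips under negative", {
  set.seed(402)
  base <- rnorm(10)
  ch0 <- rbind(data.frame(species = "a", year = 1:10, delta = base),
               data.frame(species = "b", year = 1:10, delta = rnorm(10)))
  m0 <- suppressMessages(asynchrony_matrix(ch0, 5L))$M["a", "b"]
  # adding a constant to the whole index series leaves deltas unchanged
  panel <- panel_from_deltas(list(a = base, b = ch0$delta[ch0$species == "b"]))
  panel$index[panel$species == "a"] <- panel$index[panel$species == "a"] + 7
  m_shift <- suppressMessages(
    asynchrony_matrix(interannual_change(panel), 5L))$M["a", "b"]
  expect_equal(m_shift, m0)
  ch_pos <- ch0; ch_pos$delta[ch_pos$species == "a"] <- 3.2 * base
  expect_equal(suppressMessages(asynchrony_matrix(ch_pos, 5L))$M["a", "b"], m0)
  ch_neg <- ch0; ch_neg$delta[ch_neg$species == "a"] <- -base
  expect_equal(suppressMessages(asynchrony_matrix(ch_neg, 5L))$M["a", "b"], 1 - m0)
})

test_that("permuting species labels permutes M identically", {
  set.seed(403)
  ch <- do.call(rbind, lapply(letters[1:5], function(s)
    data.frame(species = s, year = 1:12, delta = rnorm(12))))
  M1 <- suppressMessages(asynchrony_matrix(ch, 5L))$M
  perm <- c("c", "a", "e", "b", "d")
  ch2 <- ch; ch2$species <- perm[match(ch$species, letters[1:5])]
  M2 <- suppressMessages(asynchrony_matrix(ch2, 5L))$M
  # renaming a -> c etc. must carry entries with the labels
  expect_equal(unname(M2[perm, perm]), unname(M1))
})

test_that("panel and matrix CSV round trips are exact and errors are reported", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  set.seed(404)
  D <- random_dist(5)
  write_matrix(D, tmp)
  expect_equal(read_matrix(tmp), D, ignore_attr = TRUE)

  ptmp <- withr::local_tempfile(fileext = ".csv")
  panel <- abundance_panel(rep(c("x", "y", "z"), each = 3),
                           rep(2001:2003, 3), rnorm(9))
  utils::write.csv(panel, ptmp, row.names = FALSE)
  rt <- read_panel(ptmp)
  expect_equal(rt$index, panel$index)
  expect_equal(length(unique(rt$species)), 3L)

  dup <- rbind(panel, panel[1, ])
  utils::write.csv(dup, ptmp, row.names = FALSE)
  expect_error(read_panel(ptmp), "duplicate.*10")
})
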