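test_that("cumulative-proportion transform reproduces the hand example", {
  m <- toy_matrix(matrix(c(1, 2, 3, 4)), features = paste0("g", 1:4),
                  samples = "s1", scale = "linear")
  out <- cumulative_proportion_transform(m)
  # descending cumsums 4, 7, 9, 10 over total 10
  expect_equal(unname(unclass(out)[, 1]), c(0.0, 0.1, 0.3, 0.6))
  expect_identical(rownames(out), rownames(m))
})

test_that("transform is scale invariant, monotone, and tie-deterministic", {
  set.seed(61)
  v <- matrix(rexp(60), 12, 5)
  m <- toy_matrix(v, scale = "linear")
  base <- unclass(cumulative_proportion_transform(m))[, ]
  # exact invariance to positive per-sample scaling
  scl <- runif(5, 0.1, 40)
  m2 <- toy_matrix(sweep(v, 2, scl, "*"), scale = "linear")
  expect_equal(unclass(cumulative_proportion_transform(m2))[, ], base,
               tolerance = 1e-12)
  # monotone within a sample: higher input implies >= transformed value
  for (j in 1:5) {
    o <- order(v[, j])
    expect_true(all(diff(base[o, j]) >= 0))
    expect_true(all(diff(base[o, j]) > 0))  # strict when untied
  }
  # all values in [0, 1)
  expect_true(all(base >= 0 & base < 1))
  # tied genes share the block-end value, independent of row order
  vt <- matrix(c(2, 2, 1, 5), 4, 1)
  mt <- toy_matrix(vt, scale = "linear")
  outt <- unclass(cumulative_proportion_transform(mt))[, 1]
  expect_equal(unname(outt[1]), unname(outt[2]))
  expect_equal(unname(outt), c(0.1, 0.1, 0, 0.5))
  perm <- c(4, 1, 3, 2)
  mt2 <- toy_matrix(vt[perm, , drop = FALSE],
                    features = paste0("f", perm), scale = "linear")
  expect_equal(unname(unclass(cumulative_proportion_transform(mt2))[, 1]),
               unname(outt[perm]))
  # constant sample maps to all zeros under the tie rule
  mc <- toy_matrix(matrix(3, 4, 1), scale = "linear")
  expect_equal(unname(unclass(cumulative_proportion_transform(mc))[, 1]),
               rep(0, 4))
})

test_that("transform refuses log or invalid input explicitly", {
  m <- toy_matrix(matrix(1:6, 3, 2), scale = "log")
  expect_error(cumulative_proportion_transform(m), "from_log2")
  # de-logging route: 2^x then transform
  out <- cumulative_proportion_transform(m, from_log2 = TRUE)
  direct <- cumulative_proportion_transform(
    toy_matrix(2^matrix(1:6, 3, 2), scale = "linear"))
  expect_equal(unclass(out)[, ], unclass(direct)[, ])
  expect_error(cumulative_proportion_transform(
    toy_matrix(matrix(c(-1, 2, 3, 4), 2), scale = "linear")), "negative")
  expect_error(cumulative_proportion_transform(
    toy_matrix(matrix(c(0, 0, 1, 2), 2), scale = "linear")), "zero-total")
})

test_that("shared-gene intersection restricts both matrices identically", {
  a <- toy_matrix(matrix(rnorm(8), 4, 2), features = c("A", "B", "C", "D"))
  b <- toy_matrix(matrix(rnorm(6), 3, 2), features = c("B", "C", "E"))
  expect_message(out <- intersect_shared_genes(a, b), "2 shared")
  expect_identical(rownames(out$a), rownames(out$b))
  expect_setequal(rownames(out$a), c("B", "C"))
  expect_equal(unclass(out$a)["B", ], unclass(a)["B", ])
  same <- suppressMessages(intersect_shared_genes(a, a))
  expect_equal(unclass(same$a)[, ], unclass(a)[, ])
  c2 <- toy_matrix(matrix(rnorm(4), 2, 2), features = c("X", "Y"))
  expect_error(intersect_shared_genes(a, c2), "no shared")
})

test_that("ortholog pairing concatenates species and is row-order invariant", {
  set.seed(62)
  h <- toy_matrix(matrix(rexp(10), 5, 2), features = paste0("H", 1:5),
                  samples = c("h1", "h2"), scale = "linear")
  mo <- toy_matrix(matrix(rexp(10), 5, 2), features = paste0("m", 1:5),
                   samples = c("m1", "m2"), scale = "linear")
  map <- ortholog_map(paste0("H", c(1, 3, 5)), paste0("m", c(2, 3, 4)))
  co <- pair_orthologs(h, mo, map)
  expect_equal(nrow(co$matrix), 3)
  expect_equal(ncol(co$matrix), 4)
  expect_equal(unname(co$species), c("human", "human", "mouse", "mouse"))
  expect_equal(rownames(co$matrix)[1], "H1|m2")
  expect_equal(unname(unclass(co$matrix)["H3|m3", c("m1", "m2")]),
               unname(unclass(mo)["m3", ]))
  # row-shuffled inputs give the same cohort
  hs <- h[sample(5), ]
  mos <- mo[sample(5), ]
  co2 <- pair_orthologs(hs, mos, map)
  expect_equal(unclass(co2$matrix)[rownames(co$matrix), ],
               unclass(co$matrix)[, ])
  badmap <- ortholog_map("H9", "m9")
  expect_error(pair_orthologs(h, mo, badmap), "no ortholog pair")
})

test_that("correlogram equals the per-pair rank kernel with species summary", {
  set.seed(63)
  b <- rexp(30)
  mk <- function(k, prefix) toy_matrix(
    b * exp(matrix(rnorm(30 * k, sd = 0.2), 30, k)),
    features = paste0("G", 1:30), samples = paste0(prefix, 1:k),
    scale = "linear")
  h <- mk(3, "h"); mo <- mk(3, "m")
  map <- ortholog_map(paste0("G", 1:30), paste0("G", 1:30))
  co <- pair_orthologs(cumulative_proportion_transform(h),
                       cumulative_proportion_transform(mo), map)
  cg <- correlogram(co)
  v <- unclass(co$matrix)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(cg$matrix[i, j],
                 cor_record(v[, i], v[, j], method = "spearman")$r,
                 tolerance = 1e-12)
  expect_named(cg$summary, c("within_human", "within_mouse", "between"))
  # duplicated sample: off-diagonal 1 with itself
  co2 <- co
  co2$matrix <- expr_matrix(cbind(v, dup = v[, 1]), scale = "linear")
  co2$species <- c(co$species, dup = "human")
  cg2 <- correlogram(co2)
  expect_equal(cg2$matrix["h1", "dup"], 1)
})

test_that("per-gene extraction echoes values with sort-oracle median and IQR", {
  set.seed(64)
  h <- toy_matrix(matrix(rexp(12), 3, 4), features = c("A", "B", "C"),
                  samples = paste0("h", 1:4), scale = "linear")
  mo <- toy_matrix(matrix(rexp(9), 3, 3), features = c("a", "b", "c"),
                   samples = paste0("m", 1:3), scale = "linear")
  map <- ortholog_map(c("A", "B", "C"), c("a", "b", "c"))
  co <- pair_orthologs(h, mo, map)
  gl <- extract_gene_levels(co, "B", "b")
  expect_equal(gl$table$value[gl$table$species == "human"],
               unname(unclass(h)["B", ]))
  hv <- sort(unname(unclass(h)["B", ]))
  expect_equal(gl$stats$median[gl$stats$species == "human"],
               (hv[2] + hv[3]) / 2)
  expect_equal(gl$stats$iqr[gl$stats$species == "human"],
               quantile(hv, 0.75, names = FALSE) -
                 quantile(hv, 0.25, names = FALSE))
  expect_error(extract_gene_levels(co, "Z", "z"), "absent")
  # single-sample species: IQR 0 and flagged
  mo1 <- mo[, 1]
  co1 <- pair_orthologs(h, mo1, map)
  gl1 <- extract_gene_levels(co1, "B", "b")
  st <- gl1$stats[gl1$stats$species == "mouse", ]
  expect_equal(st$iqr, 0)
  expect_false(st$iqr_defined)
})
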