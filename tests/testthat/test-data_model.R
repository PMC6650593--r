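test_that("counts are closed to per-sample proportions, idempotently", {
  v <- matrix(c(2, 3, 5, 1, 4, 5), 2, 3, byrow = TRUE,
              dimnames = list(NULL, c("OTU1", "OTU2", "OTU3")))
  tab <- tiny_table(v)
  expect_equal(unname(rowSums(tab$values)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(tab$values[1, ]), c(0.2, 0.3, 0.5))
  tab2 <- abundance_table(tab$values, tab$samples, tab$feature_class)
  expect_equal(tab2$values, tab$values)
})

test_that("environmental columns are exempt from closure", {
  v <- cbind(OTU1 = c(2, 1), OTU2 = c(2, 3), temperature = c(18, 25))
  fc <- c(OTU1 = "non_cyano", OTU2 = "non_cyano", temperature = "env")
  tab <- tiny_table(v, feature_class = fc)
  expect_equal(unname(tab$values[, "temperature"]), c(18, 25))
  expect_equal(unname(rowSums(tab$values[, 1:2])), c(1, 1))
})

test_that("duplicate sample keys and negative values are rejected", {
  v <- matrix(1:4, 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(tiny_table(v, dates = c("2016-01", "2016-01")),
               "duplicate sample keys.*2016-01")
  v2 <- matrix(c(-1, 1, 1, 1), 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(tiny_table(v2), "negative")
  v3 <- matrix(1:4, 2, 2, dimnames = list(NULL, c("A", "A")))
  expect_error(tiny_table(v3), "duplicate feature")
})

test_that("sub-month timestamps are truncated to year-month", {
  v <- matrix(c(1, 1), 1, 2, dimnames = list(NULL, c("A", "B")))
  tab <- tiny_table(v, dates = "2016-07-15")
  expect_equal(tab$samples$date, "2016-07")
})

test_that("TSV write/read round trip preserves values to 12 significant digits", {
  ds <- generate_dataset(generator_config(n_otus = 10, n_months = 6,
                                          n_sites = 1, n_depths = 1,
                                          n_spurious = 0, seed = 3))
  f <- tempfile(fileext = ".tsv")
  write_abundance_table(ds$table, f)
  back <- read_abundance_table(f, env_features = features(ds$table, "env"))
  expect_equal(back$values, ds$table$values, tolerance = 1e-12)
  expect_equal(back$samples, ds$table$samples)
})

test_that("malformed header is reported with the file name", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t2"), f)
  expect_error(read_abundance_table(f), "malformed header")
})

test_that("mothur shared dialect maps Groups through sidecar metadata", {
  f <- tempfile(fileext = ".shared")
  writeLines(c("label\tGroup\tnumOtus\tOTU1\tOTU2",
               "0.01\tJun16\t2\t6\t4",
               "0.01\tJul16\t2\t1\t9"), f)
  meta <- data.frame(Group = c("Jun16", "Jul16"), site = "MG1", depth = 0,
                     date = c("2016-06", "2016-07"))
  tab <- read_abundance_table(f, dialect = "mothur_shared", meta = meta)
  expect_equal(unname(tab$values[, "OTU1"]), c(0.6, 0.1))
  expect_equal(tab$samples$site, c("MG1", "MG1"))
})

test_that("taxonomy assigns the cyanobacterial feature class", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("site\tdepth\tdate\tOTU1\tOTU2",
               "S1\t0\t2016-06\t5\t5",
               "S1\t0\t2016-07\t2\t8"), f)
  tax <- taxonomy_map(c("OTU1", "OTU2"),
                      c("Bacteria;Cyanobacteria;x;y;z;Microcystis",
                        "Bacteria;Proteobacteria;a;b;c;d"))
  tab <- read_abundance_table(f, taxonomy = tax)
  expect_equal(unname(tab$feature_class), c("cyano", "non_cyano"))
})

test_that("prevalence filter keeps 14/69 and drops 13/69 occurrence", {
  n <- 69
  v <- cbind(kept = c(rep(1, 14), rep(0, n - 14)),
             dropped = c(rep(1, 13), rep(0, n - 13)),
             common = rep(1, n))
  tab <- tiny_table(v, dates = sprintf("%04d-%02d", 2000 + (0:68) %/% 12,
                                       (0:68) %% 12 + 1))
  out <- prevalence_filter(tab, min_prevalence = 0.20)
  expect_setequal(features(out), c("kept", "common"))
})

test_that("prevalence filter keeps environmental features and does not renormalize", {
  v <- cbind(A = c(1, 0, 0, 0), B = c(1, 1, 1, 1), chl = c(9, 9, 9, 9))
  fc <- c(A = "non_cyano", B = "non_cyano", chl = "env")
  tab <- tiny_table(v, feature_class = fc)
  out <- prevalence_filter(tab, min_prevalence = 1.0)
  expect_setequal(features(out), c("B", "chl"))
  # B keeps its fraction of the original community (0.5 in sample 1)
  expect_equal(unname(out$values[1, "B"]), 0.5)
  expect_error(prevalence_filter(out, min_prevalence = 1.0,
                                 detection_threshold = 2),
               "no features retained")
})

test_that("prevalence filter is monotone in min_prevalence", {
  set.seed(42)
  v <- matrix(rbinom(200, 1, 0.4) * runif(200), 20, 10,
              dimnames = list(NULL, paste0("O", 1:10)))
  v[, 1] <- 1  # guard against an empty result
  tab <- tiny_table(v, dates = sprintf("%04d-%02d", 2000 + (0:19) %/% 12,
                                       (0:19) %% 12 + 1))
  kept <- lapply(c(0.1, 0.3, 0.5, 0.8), function(q)
    features(prevalence_filter(tab, q)))
  for (i in 2:4) expect_true(all(kept[[i]] %in% kept[[i - 1]]))
})

test_that("split_partitions partitions OTUs and concatenation restores them", {
  v <- cbind(C1 = c(.2, .1), C2 = c(.2, .2), N1 = c(.2, .3),
             N2 = c(.2, .2), N3 = c(.2, .2))
  fc <- c(C1 = "cyano", C2 = "cyano", N1 = "non_cyano", N2 = "non_cyano",
          N3 = "non_cyano")
  tab <- tiny_table(v, feature_class = fc, normalize = FALSE)
  parts <- split_partitions(tab)
  expect_equal(ncol(parts$cyano$values), 2)
  expect_equal(ncol(parts$non_cyano$values), 3)
  expect_setequal(c(features(parts$cyano), features(parts$non_cyano)),
                  features(tab))
  recon <- cbind(parts$cyano$values, parts$non_cyano$values)
  expect_equal(recon[, features(tab)], tab$values)
})

test_that("split_partitions renormalizes within a partition on request", {
  v <- cbind(C1 = c(.5, .5), N1 = c(.2, .3), N2 = c(.3, .2))
  fc <- c(C1 = "cyano", N1 = "non_cyano", N2 = "non_cyano")
  tab <- tiny_table(v, feature_class = fc, normalize = FALSE)
  parts <- split_partitions(tab, renormalize = TRUE)
  expect_equal(unname(parts$non_cyano$values[1, ]), c(0.4, 0.6))
})

test_that("an all-cyanobacterial table yields an empty partition with warning", {
  v <- cbind(C1 = c(.5, .5), C2 = c(.5, .5))
  tab <- tiny_table(v, feature_class = c(C1 = "cyano", C2 = "cyano"),
                    normalize = FALSE)
  expect_warning(parts <- split_partitions(tab), "non_cyano.*empty")
  expect_null(parts$non_cyano)
})

test_that("split_series orders by date and records missing months", {
  v <- matrix(runif(8), 4, 2, dimnames = list(NULL, c("A", "B")))
  tab <- tiny_table(v, dates = c("2016-09", "2016-06", "2016-07", "2016-10"))
  sets <- split_series(tab)
  expect_length(sets, 1)
  expect_equal(sets[[1]]$samples$date,
               c("2016-06", "2016-07", "2016-09", "2016-10"))
  expect_length(attr(sets[[1]], "missing_months"), 1)
})
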