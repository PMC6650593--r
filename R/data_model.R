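#' @useDynLib mran, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats qnorm approx rnorm runif rgamma sd var setNames p.adjust
#' @importFrom utils read.delim write.table head combn
NULL

# ---- abundance_table: samples x features with sample keys and feature classes

#' Construct an abundance table
#'
#' The central container of the pipeline: a samples x features matrix of
#' relative abundances (OTUs) and raw environmental measurements, keyed by
#' (site, depth, date). OTU rows are closed to proportions; environmental
#' columns are carried alongside so the network stage can treat them as
#' ordinary nodes.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param samples data.frame with columns `site`, `depth` (non-negative
#'   metres) and `date` (`"YYYY-MM"` strings; finer timestamps are
#'   truncated to month resolution).
#' @param feature_class named character vector over the columns of
#'   `values`, each one of `"cyano"`, `"non_cyano"`, `"env"`.
#' @param normalize close OTU columns to per-sample proportions. Already
#'   proportional tables pass through unchanged.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, samples, feature_class = NULL,
                            normalize = TRUE) {
  values <- as.matrix(values)
  rownames(values) <- NULL
  if (is.null(colnames(values))) stop("`values` must have feature names")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values))) stop("non-finite abundance values")
  stopifnot(is.data.frame(samples),
            all(c("site", "depth", "date") %in% names(samples)))
  if (nrow(samples) != nrow(values))
    stop("`samples` and `values` disagree on the number of samples")
  if (any(samples$depth < 0)) stop("negative depth")
  samples$date <- normalize_month(samples$date)
  key <- sample_key(samples)
  if (anyDuplicated(key))
    stop("duplicate sample keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (is.null(feature_class)) {
    feature_class <- setNames(rep("non_cyano", ncol(values)), colnames(values))
  }
  feature_class <- feature_class[colnames(values)]
  if (any(is.na(feature_class)))
    stop("feature_class missing for some features")
  if (!all(feature_class %in% c("cyano", "non_cyano", "env")))
    stop("feature_class values must be 'cyano', 'non_cyano' or 'env'")
  otu <- feature_class != "env"
  if (any(otu)) {
    if (any(values[, otu, drop = FALSE] < 0))
      stop("negative OTU abundance values")
    if (normalize) {
      rs <- rowSums(values[, otu, drop = FALSE])
      if (any(rs <= 0)) stop("sample with zero total OTU abundance")
      values[, otu] <- values[, otu, drop = FALSE] / rs
    }
  }
  structure(list(values = values,
                 samples = samples[, c("site", "depth", "date")],
                 feature_class = feature_class),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  fc <- table(factor(x$feature_class, c("cyano", "non_cyano", "env")))
  cat(sprintf(paste0("abundance_table: %d samples x %d features ",
                     "(%d cyano, %d non-cyano OTUs, %d environmental)\n"),
              nrow(x$values), ncol(x$values),
              fc[["cyano"]], fc[["non_cyano"]], fc[["env"]]))
  cat(sprintf("sites: %s | depths: %s | months: %s..%s\n",
              paste(unique(x$samples$site), collapse = ","),
              paste(unique(x$samples$depth), collapse = ","),
              min(x$samples$date), max(x$samples$date)))
  invisible(x)
}

sample_key <- function(samples) {
  paste(samples$site, samples$depth, samples$date, sep = "|")
}

# Truncate dates to "YYYY-MM"; accepts YYYY-MM, YYYY-MM-DD, Date.
normalize_month <- function(date) {
  if (inherits(date, "Date")) return(format(date, "%Y-%m"))
  date <- as.character(date)
  ok <- grepl("^\\d{4}-\\d{2}", date)
  if (!all(ok)) stop("unparseable date(s): ",
                     paste(unique(date[!ok]), collapse = ", "))
  substr(date, 1L, 7L)
}

# Months since year 0 - gives an integer grid for interpolation and gaps.
month_index <- function(ym) {
  y <- as.integer(substr(ym, 1, 4))
  m <- as.integer(substr(ym, 6, 7))
  y * 12L + (m - 1L)
}

#' Feature identifiers of an abundance table
#' @param table an `abundance_table`.
#' @param class optional subset of `c("cyano", "non_cyano", "env")`.
#' @return Character vector of feature names.
#' @export
features <- function(table, class = NULL) {
  f <- colnames(table$values)
  if (!is.null(class)) f <- f[table$feature_class %in% class]
  f
}

# ---- IO ------------------------------------------------------------------

#' Read an abundance table from disk
#'
#' Two dialects are supported: a plain TSV whose first three columns are
#' `site`, `depth`, `date` followed by one column per feature, and the
#' mothur "shared" layout (`label`, `Group`, `numOtus`, then OTU counts)
#' with a sidecar metadata table mapping each `Group` to a sample key.
#' Counts are closed to per-sample relative abundances over the OTU
#' columns; environmental columns are exempt.
#'
#' @param path path to the table.
#' @param dialect `"tsv"` or `"mothur_shared"`.
#' @param meta for `mothur_shared`: data.frame (or TSV path) with columns
#'   `Group`, `site`, `depth`, `date`.
#' @param taxonomy optional [taxonomy_map()]; OTUs whose lineage contains
#'   the phylum Cyanobacteria are classed `"cyano"`, the rest
#'   `"non_cyano"`.
#' @param env_features names of columns holding environmental variables
#'   (exempt from closure; classed `"env"`).
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, dialect = c("tsv", "mothur_shared"),
                                 meta = NULL, taxonomy = NULL,
                                 env_features = character()) {
  dialect <- match.arg(dialect)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "tsv") {
    need <- c("site", "depth", "date")
    if (!all(need %in% names(df)))
      stop("malformed header in ", path, ": expected columns ",
           paste(need, collapse = ", "), " (line 1)")
    samples <- df[need]
    vals <- as.matrix(df[setdiff(names(df), need)])
  } else {
    need <- c("label", "Group", "numOtus")
    if (!all(need %in% names(df)))
      stop("malformed mothur shared header in ", path, " (line 1)")
    if (is.character(meta) && length(meta) == 1L)
      meta <- read.delim(meta, stringsAsFactors = FALSE)
    if (is.null(meta) || !all(c("Group", "site", "depth", "date") %in% names(meta)))
      stop("mothur_shared dialect needs `meta` with Group, site, depth, date")
    idx <- match(df$Group, meta$Group)
    if (any(is.na(idx)))
      stop("Groups missing from metadata: ",
           paste(df$Group[is.na(idx)], collapse = ", "))
    samples <- meta[idx, c("site", "depth", "date")]
    vals <- as.matrix(df[setdiff(names(df), need)])
  }
  storage.mode(vals) <- "double"
  if (any(is.na(vals))) stop("non-numeric or missing values in ", path)
  if (any(vals[, setdiff(colnames(vals), env_features), drop = FALSE] < 0))
    stop("negative abundance value in ", path)
  fc <- setNames(rep("non_cyano", ncol(vals)), colnames(vals))
  fc[colnames(vals) %in% env_features] <- "env"
  if (!is.null(taxonomy)) {
    otus <- names(fc)[fc != "env"]
    fc[otus[is_cyanobacterial(taxonomy, otus)]] <- "cyano"
  }
  abundance_table(vals, samples, fc)
}

#' Write an abundance table as TSV
#'
#' Inverse of [read_abundance_table()] for the `tsv` dialect; values are
#' printed with 15 significant digits so a read/write round trip is
#' faithful to 12 significant digits.
#'
#' @param table an `abundance_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  df <- cbind(table$samples,
              as.data.frame(signif(table$values, 15), check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- taxonomy ------------------------------------------------------------

#' Build a taxonomy map
#'
#' @param otu_id character vector of OTU identifiers.
#' @param lineage semicolon-separated ranked lineage strings
#'   (domain;phylum;...;genus); unknown OTUs may be `"unclassified"`.
#' @return Named character vector (class `taxonomy_map`).
#' @export
taxonomy_map <- function(otu_id, lineage) {
  stopifnot(length(otu_id) == length(lineage))
  structure(setNames(as.character(lineage), otu_id), class = "taxonomy_map")
}

#' Read a two-column OTU/lineage TSV into a taxonomy map
#' @param path TSV with columns `otu_id` and `lineage`.
#' @return A [taxonomy_map()].
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("otu_id", "lineage") %in% names(df)))
    stop("taxonomy file needs columns otu_id, lineage")
  taxonomy_map(df$otu_id, df$lineage)
}

lineage_ranks <- function(taxonomy, otu) {
  lin <- unname(taxonomy[otu])
  lapply(lin, function(l) {
    if (is.na(l)) character() else trimws(strsplit(l, ";", fixed = TRUE)[[1]])
  })
}

is_cyanobacterial <- function(taxonomy, otus) {
  vapply(lineage_ranks(taxonomy, otus),
         function(r) any(tolower(r) == "cyanobacteria"), logical(1))
}

# ---- filtering and partitioning -----------------------------------------

#' Prevalence filter
#'
#' Keeps OTUs detected (value strictly above `detection_threshold`) in at
#' least a fraction `min_prevalence` of samples; environmental features
#' are always retained. Abundances are deliberately not renormalised, so
#' retained values stay fractions of the original whole community.
#'
#' @param table an `abundance_table`.
#' @param min_prevalence minimum occurrence fraction, default 0.20.
#' @param detection_threshold value above which a feature counts as
#'   present, default 0.
#' @return Filtered `abundance_table`.
#' @export
prevalence_filter <- function(table, min_prevalence = 0.20,
                              detection_threshold = 0) {
  stopifnot(min_prevalence > 0, min_prevalence <= 1, detection_threshold >= 0)
  occ <- colMeans(table$values > detection_threshold)
  keep <- occ >= min_prevalence | table$feature_class == "env"
  if (!any(keep & table$feature_class != "env"))
    stop("no features retained at min_prevalence = ", min_prevalence)
  out <- table
  out$values <- table$values[, keep, drop = FALSE]
  out$feature_class <- table$feature_class[keep]
  out
}

#' Split a table into cyanobacterial and non-cyanobacterial partitions
#'
#' Environmental features belong to neither partition and are dropped.
#' Values are copied unchanged unless `renormalize` recomputes
#' within-partition proportions.
#'
#' @param table an `abundance_table` with feature classes assigned.
#' @param renormalize close each partition to per-sample proportions.
#' @return `list(cyano = , non_cyano = )` of abundance tables.
#' @export
split_partitions <- function(table, renormalize = FALSE) {
  take <- function(class) {
    keep <- table$feature_class == class
    if (!any(keep)) {
      warning("partition '", class, "' is empty")
      return(NULL)
    }
    vals <- table$values[, keep, drop = FALSE]
    if (renormalize) {
      rs <- rowSums(vals)
      vals[rs > 0, ] <- vals[rs > 0, , drop = FALSE] / rs[rs > 0]
    }
    abundance_table(vals, table$samples, table$feature_class[keep],
                    normalize = FALSE)
  }
  list(cyano = take("cyano"), non_cyano = take("non_cyano"))
}

#' Split an abundance table into per-(site, depth) time series sets
#'
#' @param table an `abundance_table`.
#' @return Named list (one element per site|depth) of abundance tables
#'   ordered by date, each annotated with its missing months.
#' @export
split_series <- function(table) {
  grp <- paste(table$samples$site, table$samples$depth, sep = "|")
  out <- lapply(split(seq_len(nrow(table$values)), grp), function(i) {
    i <- i[order(month_index(table$samples$date[i]))]
    if (length(i) < 2L) stop("series with fewer than 2 time points")
    tab <- abundance_table(table$values[i, , drop = FALSE],
                           table$samples[i, , drop = FALSE],
                           table$feature_class, normalize = FALSE)
    mi <- month_index(tab$samples$date)
    full <- seq(min(mi), max(mi))
    attr(tab, "missing_months") <- setdiff(full, mi)
    tab
  })
  out[order(names(out))]
}
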