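# Collapse of OTU abundances into functional-group abundances through a
# taxon -> function mapping (FAPROTAX-style), grouped by module and month.

#' Build a function map
#'
#' @param x named list: function label -> character vector of taxon
#'   selectors (exact taxon strings at any rank, or OTU ids).
#' @return A `function_map`.
#' @export
function_map <- function(x) {
  stopifnot(is.list(x), length(x) > 0, !is.null(names(x)),
            !anyDuplicated(names(x)))
  if (any(lengths(x) == 0)) stop("empty selector set for: ",
                                 paste(names(x)[lengths(x) == 0],
                                       collapse = ", "))
  structure(lapply(x, as.character), class = "function_map")
}

#' Read a function map from disk
#'
#' Two formats: a two-column TSV (`function`, `taxon_selector`), or the
#' FAPROTAX-like layout where a `label:` header line opens a block of
#' indented/plain selector lines (comments `#` and blank lines ignored,
#' `*`-only selectors skipped).
#'
#' @param path input file.
#' @param format `"tsv"` or `"faprotax"`.
#' @return A [function_map()].
#' @export
read_function_map <- function(path, format = c("tsv", "faprotax")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("function.", "taxon_selector") %in% names(df)) &&
        !all(c("function", "taxon_selector") %in% names(df))) {
      names(df)[1:2] <- c("fun", "taxon_selector")
    } else {
      names(df)[names(df) %in% c("function.", "function")] <- "fun"
    }
    return(function_map(split(df$taxon_selector, df$fun)))
  }
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  out <- list(); current <- NULL
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (grepl(":\\s*$", ln) && !grepl("^\\s", ln)) {
      current <- sub(":\\s*$", "", trimws(ln))
      out[[current]] <- character(0)
    } else if (!is.null(current)) {
      sel <- trimws(ln)
      if (sel != "*") out[[current]] <- c(out[[current]], sel)
    }
  }
  function_map(out[lengths(out) > 0])
}

# which OTUs match a selector set: exact OTU id, or exact taxon string at
# any rank of the lineage (no fuzzy matching)
match_function <- function(selectors, otus, ranks) {
  otus[otus %in% selectors |
         vapply(ranks, function(r) any(r %in% selectors), logical(1))]
}

#' Collapse module abundances into functional-group abundances
#'
#' For each module and month, a function's value is the mean (over the
#' month's samples) of the summed relative abundances of module-member
#' OTUs mapped to that function - the per-module function composition
#' scaled by the module's total OTU abundance. OTUs mapped to several
#' functions contribute fully to each; unmapped OTUs contribute nowhere;
#' functions with no member OTU present give explicit zero rows.
#'
#' @param table an [abundance_table()].
#' @param partition a [louvain_partition()] over (a subset of) the
#'   table's OTU features.
#' @param fmap a [function_map()].
#' @param taxonomy a [taxonomy_map()] resolving OTUs to lineages; OTUs
#'   absent from it count as unmapped, with a warning.
#' @param modules modules to profile (default: the partition's major
#'   modules).
#' @return A `function_table`: list with `values` (function x
#'   module@month matrix), `by_module` (function x module, averaged over
#'   months), `long` data.frame and `normalization = "none"`.
#' @export
collapse_functions <- function(table, partition, fmap, taxonomy,
                               modules = partition$major_modules) {
  stopifnot(inherits(fmap, "function_map"))
  if (length(fmap) == 0) stop("empty function map")
  otus <- intersect(names(partition$membership),
                    features(table, c("cyano", "non_cyano")))
  unknown <- otus[!otus %in% names(taxonomy)]
  if (length(unknown))
    warning(length(unknown), " OTU(s) missing from taxonomy are unmapped")
  ranks <- lineage_ranks(taxonomy, otus)
  names(ranks) <- otus
  members <- lapply(fmap, match_function, otus = otus, ranks = ranks)
  months <- sort(unique(table$samples$date))
  funs <- names(fmap)
  long <- expand.grid(fun = funs, module = modules, month = months,
                      stringsAsFactors = FALSE)
  long$value <- mapply(function(fn, mod, mth) {
    mem <- intersect(members[[fn]],
                     names(partition$membership)[partition$membership == mod])
    if (length(mem) == 0) return(0)
    rows <- table$samples$date == mth
    mean(rowSums(table$values[rows, mem, drop = FALSE]))
  }, long$fun, long$module, long$month)
  grp <- paste(long$module, long$month, sep = "@")
  values <- matrix(long$value, nrow = length(funs),
                   dimnames = list(funs, unique(grp)))
  by_module <- matrix(NA_real_, length(funs), length(modules),
                      dimnames = list(funs, modules))
  for (mod in modules)
    by_module[, mod] <- rowMeans(values[, paste(mod, months, sep = "@"),
                                        drop = FALSE])
  structure(list(values = values, by_module = by_module, long = long,
                 normalization = "none"),
            class = "function_table")
}

#' Normalise a function table
#'
#' @param ftable a `function_table`.
#' @param mode `"none"` (identity), `"per_group_fraction"` (each column
#'   divided by its sum; all-zero columns stay zero) or
#'   `"min_max_per_function"` (each row scaled to [0, 1] for heatmap
#'   display).
#' @return The normalised `function_table` (both `values` and
#'   `by_module` transformed; `normalization` tag updated).
#' @export
normalize_function_table <- function(ftable,
                                     mode = c("none", "per_group_fraction",
                                              "min_max_per_function")) {
  mode <- match.arg(mode)
  norm <- function(m) {
    if (mode == "none") return(m)
    if (mode == "per_group_fraction") {
      cs <- colSums(m)
      cs[cs == 0] <- 1
      return(sweep(m, 2, cs, `/`))
    }
    t(apply(m, 1, function(v) {
      rng <- range(v)
      if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
    }))
  }
  ftable$values <- norm(ftable$values)
  ftable$by_module <- norm(ftable$by_module)
  ftable$normalization <- mode
  ftable
}

#' @export
print.function_table <- function(x, ...) {
  cat(sprintf("function_table: %d functions x %d module-months (%s)\n",
              nrow(x$values), ncol(x$values), x$normalization))
  invisible(x)
}
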