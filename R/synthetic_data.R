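#' Configuration for the synthetic multi-site time-series generator
#'
#' Defaults mirror the field-study design the pipeline targets: 3 river
#' sites x 2 depths sampled monthly for 15 months (June through August of
#' the following year), a few hundred prevalent OTUs plus 11 environmental
#' variables, with roughly a fifth of the monthly samples missing.
#'
#' @param n_sites,n_depths,n_months sampling design (defaults 3, 2, 15).
#' @param n_otus number of OTUs (default 200).
#' @param n_env number of environmental variables (default 11; the first
#'   are temperature, pH, DO, TN, TDN, TP, TDP, chl_a, precipitation,
#'   discharge, turbidity).
#' @param n_modules number of planted modules (default 5); module 1 is the
#'   cyanobacterial bloom module.
#' @param within_module_coupling loading of each OTU on its module driver,
#'   in [0, 1] (default 0.8).
#' @param lag_fraction fraction of planted pairwise couplings given a
#'   one-month delay (default 0.2).
#' @param noise_sd standard deviation of the per-OTU latent noise
#'   (default 0.3).
#' @param dirichlet_concentration concentration of the Dirichlet
#'   resampling that closes each sample to proportions (default 500;
#'   larger = less compositional noise).
#' @param bloom_otu_peak_fraction peak relative abundance of the planted
#'   bloom OTU (default 0.4).
#' @param missing_month_fraction fraction of interior months dropped from
#'   each (site, depth) series (default 0.2, matching 69 of 90 possible
#'   samples present).
#' @param n_spurious number of site-specific spurious couplings, each
#'   planted in exactly one (site, depth) series set so that recurrence
#'   filtering provably removes them (default 6).
#' @param neg_loading_fraction fraction of OTUs with a negative loading on
#'   their module driver (default 0.05, which reproduces the roughly 9:1
#'   positive:negative edge balance typical of freshwater co-occurrence
#'   networks).
#' @param seed integer RNG seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_sites = 3, n_depths = 2, n_months = 15,
                             n_otus = 200, n_env = 11, n_modules = 5,
                             within_module_coupling = 0.8,
                             lag_fraction = 0.2, noise_sd = 0.3,
                             dirichlet_concentration = 500,
                             bloom_otu_peak_fraction = 0.4,
                             missing_month_fraction = 0.2,
                             n_spurious = 6,
                             neg_loading_fraction = 0.05,
                             seed = 1) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_sites >= 1, n_depths >= 1, n_months >= 4,
              n_otus >= 4, n_env >= 0, n_modules >= 1,
              n_modules <= n_otus,
              within_module_coupling >= 0, within_module_coupling <= 1,
              lag_fraction >= 0, lag_fraction <= 1,
              noise_sd >= 0, dirichlet_concentration > 0,
              bloom_otu_peak_fraction > 0, bloom_otu_peak_fraction < 1,
              missing_month_fraction >= 0, missing_month_fraction < 1,
              n_spurious >= 0,
              neg_loading_fraction >= 0, neg_loading_fraction < 1)
  })
  structure(cfg, class = "generator_config")
}

env_variable_names <- function(n_env) {
  base <- c("temperature", "pH", "DO", "TN", "TDN", "TP", "TDP", "chl_a",
            "precipitation", "discharge", "turbidity")
  if (n_env <= length(base)) return(base[seq_len(n_env)])
  c(base, paste0("env", seq_len(n_env - length(base))))
}

# Module drivers: seasonal harmonics over the calendar month, centred and
# orthogonalised so distinct planted modules are uncorrelated at the
# latent level (planted module membership is then identifiable ground
# truth rather than an accident of phase overlap). Module 1 carries a
# summer bloom pulse on top of the annual cycle.
module_drivers <- function(cal_month, n_modules) {
  t2 <- 2 * pi * cal_month
  pulse <- exp(-((cal_month - 7.5)^2) / (2 * 1.5^2))
  basis <- cbind(sin(2 * pi * (cal_month - 4.5) / 12) + 1.5 * pulse,
                 cos(t2 / 12), sin(t2 / 6), cos(t2 / 6),
                 sin(t2 / 4), cos(t2 / 4), sin(t2 / 3), cos(t2 / 3))
  while (ncol(basis) < n_modules)
    basis <- cbind(basis, rnorm(length(cal_month)))
  basis <- basis[, seq_len(n_modules), drop = FALSE]
  # Gram-Schmidt on centred columns
  n <- nrow(basis)
  for (k in seq_len(ncol(basis))) {
    v <- basis[, k] - mean(basis[, k])
    if (k > 1)
      for (j in seq_len(k - 1))
        v <- v - sum(v * basis[, j]) / sum(basis[, j]^2) * basis[, j]
    if (sqrt(sum(v^2)) < 1e-8) {  # degenerate: fall back to noise
      v <- rnorm(n)
      v <- v - mean(v)
      for (j in seq_len(k - 1))
        v <- v - sum(v * basis[, j]) / sum(basis[, j]^2) * basis[, j]
    }
    basis[, k] <- v
  }
  scale(basis)  # unit-sd columns
}

cyano_genera <- c("Microcystis", "Pseudanabaena", "Dolichospermum",
                  "Aphanizomenon")
noncyano_taxa <- c(
  "Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales;Comamonadaceae;Paucimonas",
  "Bacteria;Actinobacteria;Actinobacteria;Frankiales;Sporichthyaceae;hgcI_clade",
  "Bacteria;Bacteroidetes;Sphingobacteriia;Sphingobacteriales;Saprospiraceae;Haliscomenobacter",
  "Bacteria;Bacteroidetes;Cytophagia;Cytophagales;Cytophagaceae;Flectobacillus",
  "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodospirillales;Acetobacteraceae;Roseomonas",
  "Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales;Oxalobacteraceae;Herbaspirillum",
  "Bacteria;Proteobacteria;Betaproteobacteria;Nitrosomonadales;Nitrosomonadaceae;Nitrosomonas",
  "Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;Flavobacteriaceae;Flavobacterium",
  "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales;Rhodobacteraceae;Rhodobacter",
  "Bacteria;Verrucomicrobia;Verrucomicrobiae;Verrucomicrobiales;Verrucomicrobiaceae;Prosthecobacter")

#' Generate a synthetic multi-site OTU + environment dataset
#'
#' Each (site, depth) series set shares the same planted structure:
#' module-level seasonal drivers (orthogonalised harmonics; module 1 adds
#' a summer bloom pulse), per-OTU loadings of magnitude
#' `within_module_coupling` with a minority of negative signs, planted
#' pairwise couplings realised as lagged noise sharing, and Gaussian
#' latent noise. Latent values are exponentiated and closed to
#' compositions by Dirichlet resampling. A designated bloom OTU follows a
#' planted proportion trajectory peaking at `bloom_otu_peak_fraction`,
#' and chlorophyll-a is an affine function of the realised bloom-module
#' total plus noise, so bloom labelling is exercisable end to end.
#' Spurious couplings live in exactly one series set each, so the
#' recurrence filter of [build_consensus()] provably removes them.
#'
#' @param config a [generator_config()].
#' @return `list(table = , truth = )`: an [abundance_table()] and a
#'   ground-truth list with elements `planted_edges`, `spurious_edges`,
#'   `planted_modules`, `bloom_months`, `taxonomy`, `target_otu`,
#'   `latent` (per-set latent month x OTU matrices) and `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n_otus <- config$n_otus; n_months <- config$n_months
  n_modules <- config$n_modules

  # month grid starting June 2016
  start <- 2016 * 12 + 5                      # month_index of "2016-06"
  mi <- start + seq_len(n_months) - 1L
  months <- sprintf("%04d-%02d", mi %/% 12, mi %% 12 + 1L)
  cal_month <- mi %% 12 + 1L

  drivers <- module_drivers(cal_month, n_modules)
  pulse <- exp(-((cal_month - 7.5)^2) / (2 * 1.5^2))

  otus <- sprintf("OTU%04d", seq_len(n_otus))
  module_of <- sort(rep_len(seq_len(n_modules), n_otus))
  names(module_of) <- otus
  load_sign <- ifelse(runif(n_otus) < config$neg_loading_fraction, -1, 1)
  names(load_sign) <- otus
  target_otu <- otus[module_of == 1][1]
  load_sign[target_otu] <- 1
  feature_class <- setNames(ifelse(module_of == 1, "cyano", "non_cyano"), otus)
  mu <- setNames(rnorm(n_otus, 0, 0.5), otus)

  # planted pairwise couplings: consecutive members within each module
  pe <- do.call(rbind, lapply(seq_len(n_modules), function(m) {
    mem <- otus[module_of == m]
    if (length(mem) < 2) return(NULL)
    k <- (length(mem) %/% 2) * 2
    data.frame(a = mem[seq(1, k, 2)], b = mem[seq(2, k, 2)],
               stringsAsFactors = FALSE)
  }))
  pe$delay <- ifelse(runif(nrow(pe)) < config$lag_fraction,
                     sample(c(-1L, 1L), nrow(pe), replace = TRUE), 0L)
  pe$sign <- ifelse(load_sign[pe$a] * load_sign[pe$b] > 0, "+", "-")

  # spurious couplings: cross-module pairs, one series set each
  sites <- paste0("S", seq_len(config$n_sites))
  sets <- expand.grid(site = sites,
                      depth = (seq_len(config$n_depths) - 1) * 2,
                      stringsAsFactors = FALSE)
  sets <- sets[order(sets$site, sets$depth), ]
  n_sets <- nrow(sets)
  sp <- NULL
  if (config$n_spurious > 0) {
    sp <- data.frame(a = character(0), b = character(0))
    used <- character(0)
    for (k in seq_len(config$n_spurious)) {
      repeat {
        cand <- sample(otus, 2)
        if (module_of[cand[1]] != module_of[cand[2]] &&
            !(cand[2] %in% used)) break
      }
      used <- c(used, cand[2])
      sp <- rbind(sp, data.frame(a = cand[1], b = cand[2],
                                 stringsAsFactors = FALSE))
    }
    sp$sign <- "+"
    sp$set <- rep_len(seq_len(n_sets), config$n_spurious)
  }

  # planted bloom-OTU proportion trajectory and truth labels
  f_target <- 0.02 + (config$bloom_otu_peak_fraction - 0.02) * pulse / max(pulse)

  lam <- config$within_module_coupling
  rows_values <- NULL; rows_samples <- NULL
  latent_list <- vector("list", n_sets)
  bloom_truth <- NULL
  env_names <- env_variable_names(config$n_env)

  for (k in seq_len(n_sets)) {
    eps <- matrix(rnorm(n_months * n_otus, 0, config$noise_sd),
                  n_months, n_otus, dimnames = list(months, otus))
    # lagged noise sharing for planted couplings
    for (r in seq_len(nrow(pe))) {
      d <- pe$delay[r]; a <- pe$a[r]; b <- pe$b[r]
      src <- eps[, a]
      if (d != 0) {
        shifted <- rep(NA_real_, n_months)
        idx <- seq_len(n_months) - d
        ok <- idx >= 1 & idx <= n_months
        shifted[ok] <- src[idx[ok]]
        shifted[!ok] <- rnorm(sum(!ok), 0, config$noise_sd)
        src <- shifted
      }
      rho <- 0.7 * load_sign[a] * load_sign[b]
      eps[, b] <- rho * src + sqrt(1 - 0.7^2) * eps[, b]
    }
    latent <- sweep(drivers[, module_of, drop = FALSE], 2,
                    lam * load_sign, `*`) + eps
    colnames(latent) <- otus
    # spurious site-specific couplings overwrite the target's latent
    if (!is.null(sp)) for (r in which(sp$set == k)) {
      latent[, sp$b[r]] <- latent[, sp$a[r]] +
        rnorm(n_months, 0, 0.3 * max(stats::sd(latent[, sp$a[r]]), 1e-6))
    }
    latent_list[[k]] <- latent

    w <- exp(sweep(latent, 2, mu, `+`))
    # plant the bloom OTU's proportion trajectory
    other <- rowSums(w[, otus != target_otu, drop = FALSE])
    w[, target_otu] <- f_target / (1 - f_target) * other
    p <- w / rowSums(w)

    # Dirichlet closure (compositional noise)
    g <- matrix(rgamma(length(p), shape = config$dirichlet_concentration * p,
                       rate = 1), nrow(p), ncol(p), dimnames = dimnames(p))
    x <- g / rowSums(g)

    # environmental variables
    bloom_total <- rowSums(x[, module_of == 1, drop = FALSE])
    env <- matrix(NA_real_, n_months, length(env_names),
                  dimnames = list(months, env_names))
    for (e in env_names) {
      env[, e] <- switch(e,
        temperature = 20 + 8 * sin(2 * pi * (cal_month - 4.5) / 12) + rnorm(n_months, 0, 1),
        chl_a = pmax(0.1, 2 + 80 * bloom_total + rnorm(n_months, 0, 0.5)),
        pH = 8 + rnorm(n_months, 0, 0.3),
        DO = 10 + rnorm(n_months, 0, 1.5),
        TN = 3 + rnorm(n_months, 0, 0.6),
        TDN = 2.5 + rnorm(n_months, 0, 0.5),
        TP = 0.1 + abs(rnorm(n_months, 0, 0.04)),
        TDP = 0.05 + abs(rnorm(n_months, 0, 0.02)),
        precipitation = abs(rnorm(n_months, 80, 60)),
        discharge = abs(rnorm(n_months, 300, 150)),
        rnorm(n_months))
    }

    # truth labels from planted values (noise-free chl proxy)
    planned_bloom_total <- rowSums(p[, module_of == 1, drop = FALSE])
    chl_planned <- 2 + 80 * planned_bloom_total
    is_bloom <- (f_target > 0.10 & chl_planned > 15) | f_target > 0.80
    if (any(is_bloom))
      bloom_truth <- rbind(bloom_truth,
                           data.frame(site = sets$site[k], depth = sets$depth[k],
                                      date = months[is_bloom],
                                      stringsAsFactors = FALSE))

    # drop interior months
    keep <- rep(TRUE, n_months)
    n_drop <- round(config$missing_month_fraction * n_months)
    if (n_drop > 0) {
      interior <- 2:(n_months - 1)
      keep[sample(interior, min(n_drop, length(interior)))] <- FALSE
    }
    vals <- cbind(x, env)[keep, , drop = FALSE]
    rows_values <- rbind(rows_values, vals)
    rows_samples <- rbind(rows_samples,
                          data.frame(site = sets$site[k], depth = sets$depth[k],
                                     date = months[keep],
                                     stringsAsFactors = FALSE))
  }

  fc <- c(feature_class, setNames(rep("env", length(env_names)), env_names))
  table <- abundance_table(rows_values, rows_samples, fc, normalize = FALSE)

  # taxonomy: cyano OTUs get cyanobacterial genera; others get families
  # with module-biased weights so function collapse has structure
  lineage <- character(n_otus)
  cy <- module_of == 1
  lineage[cy] <- paste0("Bacteria;Cyanobacteria;Cyanobacteria;SubsectionI;FamilyI;",
                        rep_len(cyano_genera, sum(cy)))
  for (m in setdiff(seq_len(n_modules), 1)) {
    idx <- which(module_of == m)
    wts <- rep(1, length(noncyano_taxa))
    wts[((m - 2) %% length(noncyano_taxa)) + 1] <- 6   # dominant family per module
    lineage[idx] <- sample(noncyano_taxa, length(idx), replace = TRUE, prob = wts)
  }
  taxonomy <- taxonomy_map(otus, lineage)

  truth <- list(planted_edges = pe[, c("a", "b", "sign", "delay")],
                spurious_edges = sp,
                planted_modules = setNames(paste0("M", module_of), otus),
                bloom_months = bloom_truth,
                taxonomy = taxonomy,
                target_otu = target_otu,
                target_fraction = setNames(f_target, months),
                latent = setNames(latent_list,
                                  paste(sets$site, sets$depth, sep = "|")),
                config = config)
  list(table = table, truth = truth)
}

#' Write a generated dataset as a set of plain-text fixture files
#'
#' @param dataset result of [generate_dataset()].
#' @param directory output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_fixture <- function(dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(directory, f)
  write_abundance_table(dataset$table, fp("abundance.tsv"))
  write.table(dataset$table$samples, fp("metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$truth$planted_edges, fp("planted_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  mm <- data.frame(otu_id = names(dataset$truth$planted_modules),
                   module = unname(dataset$truth$planted_modules))
  write.table(mm, fp("planted_modules.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tx <- data.frame(otu_id = names(dataset$truth$taxonomy),
                   lineage = unname(unclass(dataset$truth$taxonomy)))
  write.table(tx, fp("taxonomy.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  setNames(fp(c("abundance.tsv", "metadata.tsv", "planted_edges.tsv",
                "planted_modules.tsv", "taxonomy.tsv")),
           c("abundance", "metadata", "planted_edges", "planted_modules",
             "taxonomy"))
}
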