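## Synthetic data: deterministic toy KGML pathways and two-group
## methylation/expression matrices with planted differential sites and
## methylation-coupled genes, emulating a cohort split by a binary
## molecular status (e.g. a mutation) where a subset of CpG sites is
## hyper-methylated in one group and silences its host gene's expression.

#' Generate a toy KGML pathway document
#'
#' Valid KGML with gene entries (`GENE1` ... `GENEn`) laid out on a grid and
#' relations whose subtypes cycle through activation, inhibition,
#' expression, repression, methylation and unknown. Bit-reproducible under a
#' fixed seed and parseable by [parse_kgml()].
#'
#' @param n_genes Number of gene entries.
#' @param n_relations Number of relations (at most `n_genes * (n_genes-1)`).
#' @param seed Integer seed.
#' @param n_maps Number of additional (neutral) map entries.
#' @param pathway_id,organism Identifiers stamped into the document.
#' @return Raw vector of KGML bytes.
#' @export
make_kgml <- function(n_genes, n_relations = 0, seed = 1, n_maps = 0,
                      pathway_id = "syn00001", organism = "syn") {
  stopifnot(n_genes >= 1, n_relations <= n_genes * (n_genes - 1))
  set.seed(seed)
  ncols <- ceiling(sqrt(n_genes))
  entries <- lapply(seq_len(n_genes), function(i) {
    pathway_entry(
      entry_id = as.character(i), entry_type = "gene",
      kegg_ids = paste0(organism, ":", 1000 + i),
      label = paste0("GENE", i),
      aliases = c(paste0("GENE", i), paste0("G", i, "ALT")),
      graphics = list(x = 70 + ((i - 1) %% ncols) * 110,
                      y = 60 + ((i - 1) %/% ncols) * 70,
                      width = 46, height = 17, shape = "rectangle"))
  })
  if (n_maps > 0) {
    maps <- lapply(seq_len(n_maps), function(j) {
      pathway_entry(
        entry_id = as.character(n_genes + j), entry_type = "map",
        kegg_ids = paste0("path:", organism, sprintf("%05d", j)),
        label = paste0("linked map ", j),
        aliases = paste0("linked map ", j),
        graphics = list(x = 70 + (j - 1) * 120,
                        y = 60 + (ceiling(n_genes / ncols)) * 70 + 40,
                        width = 80, height = 25, shape = "roundrectangle"))
    })
    entries <- c(entries, maps)
  }
  pairs <- expand.grid(src = seq_len(n_genes), dst = seq_len(n_genes))
  pairs <- pairs[pairs$src != pairs$dst, , drop = FALSE]
  pairs <- pairs[sample.int(nrow(pairs), n_relations), , drop = FALSE]
  subtype_cycle <- c("activation", "inhibition", "expression", "repression",
                     "methylation", "unknown")
  relations <- lapply(seq_len(nrow(pairs)), function(k) {
    pathway_relation(as.character(pairs$src[k]), as.character(pairs$dst[k]),
                     relation_class = "PPrel",
                     subtypes = subtype_cycle[(k - 1) %% 6 + 1])
  })
  g <- pathway_graph(pathway_id, organism, "synthetic pathway",
                     entries, relations)
  serialize_graph(g)
}

#' Specification for a synthetic two-group dataset
#'
#' Defaults describe a balanced two-group cohort (20 + 20 samples) with a
#' clear planted signal: planted sites have group beta means 0.2 vs 0.7
#' (a between-group difference of 0.5) with Gaussian noise of SD 0.05
#' (clipped to `[0,1]`), background sites share one mean across groups, and
#' coupled genes express at
#' `FPKM = base * 2^(-coupling_rate * beta)` of their planted site with
#' log-normal multiplicative noise — a strictly monotone-decreasing
#' coupling, so methylation and expression of those genes are strongly
#' anti-correlated.
#'
#' @param n_genes Number of genes (matching [make_kgml()] labels).
#' @param sites_per_gene CpG sites per gene.
#' @param n_per_group Samples in each group.
#' @param groups Two group labels.
#' @param n_planted_genes Number of genes whose first site is planted.
#' @param planted_means Group beta means of planted sites
#'   (`c(group1, group2)`).
#' @param background_mean Beta mean of background sites (both groups).
#' @param noise_sd Gaussian beta noise SD.
#' @param n_coupled How many planted genes get methylation-coupled
#'   expression (the first ones).
#' @param coupling_rate Log2-fold drop in FPKM per unit beta.
#' @param expr_base Baseline FPKM.
#' @param expr_noise_sdlog SD of the log-normal expression noise (natural
#'   log scale).
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 20, sites_per_gene = 3,
                           n_per_group = 20,
                           groups = c("mutant", "wild_type"),
                           n_planted_genes = 5,
                           planted_means = c(0.2, 0.7),
                           background_mean = 0.45, noise_sd = 0.05,
                           n_coupled = 3, coupling_rate = 4,
                           expr_base = 50, expr_noise_sdlog = 0.1,
                           seed = 1) {
  stopifnot(length(groups) == 2, n_planted_genes <= n_genes,
            n_coupled <= n_planted_genes, noise_sd >= 0,
            all(planted_means >= 0 & planted_means <= 1))
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic two-group methylation/expression dataset
#'
#' Writes four tab-separated files to `dir` — `methylation.tsv` (annotated
#' row keys `GENEi_cgXXXXXXXX_location`), `expression.tsv`, `grouping.tsv`
#' and `truth.tsv` (one row per CpG site with `planted` and `coupled`
#' flags, making recovery tests self-describing) — and returns the parsed
#' objects. Identical spec (including seed) gives byte-identical files.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if absent).
#' @return List with `methylation`, `expression` (`omics_matrix`),
#'   `grouping` (`sample_grouping`), `truth` (data frame) and `paths`.
#' @export
make_dataset <- function(spec = synthetic_spec(), dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  n_samples <- 2 * spec$n_per_group
  samples <- c(paste0("S", sprintf("%02d", seq_len(spec$n_per_group)), "A"),
               paste0("S", sprintf("%02d", seq_len(spec$n_per_group)), "B"))
  group_of <- rep(spec$groups, each = spec$n_per_group)
  locations <- c("upstream", "exonic", "intronic", "UTR5", "UTR3",
                 "downstream")

  n_sites <- spec$n_genes * spec$sites_per_gene
  keys <- character(n_sites)
  truth <- data.frame(key = character(n_sites), gene = character(n_sites),
                      site_id = character(n_sites),
                      planted = logical(n_sites), coupled = logical(n_sites),
                      stringsAsFactors = FALSE)
  betas <- matrix(NA_real_, nrow = n_sites, ncol = n_samples)
  planted_site_beta <- matrix(NA_real_, nrow = spec$n_planted_genes,
                              ncol = n_samples)
  k <- 0L
  for (g in seq_len(spec$n_genes)) {
    gene <- paste0("GENE", g)
    for (s in seq_len(spec$sites_per_gene)) {
      k <- k + 1L
      site_id <- sprintf("cg%08d", k)
      loc <- locations[(k - 1) %% length(locations) + 1]
      planted <- g <= spec$n_planted_genes && s == 1
      mu <- if (planted) {
        ifelse(group_of == spec$groups[1], spec$planted_means[1],
               spec$planted_means[2])
      } else {
        rep(spec$background_mean, n_samples)
      }
      b <- pmin(pmax(mu + stats::rnorm(n_samples, 0, spec$noise_sd), 0), 1)
      betas[k, ] <- b
      if (planted) planted_site_beta[g, ] <- b
      keys[k] <- paste(gene, site_id, loc, sep = "_")
      truth[k, ] <- list(keys[k], gene, site_id, planted,
                         planted && g <= spec$n_coupled)
    }
  }

  expr <- matrix(NA_real_, nrow = spec$n_genes, ncol = n_samples)
  for (g in seq_len(spec$n_genes)) {
    noise <- exp(stats::rnorm(n_samples, 0, spec$expr_noise_sdlog))
    if (g <= spec$n_coupled) {
      expr[g, ] <- spec$expr_base *
        2^(-spec$coupling_rate * planted_site_beta[g, ]) * noise
    } else {
      base_g <- spec$expr_base * 2^stats::runif(1, -1, 1)
      expr[g, ] <- base_g * noise
    }
  }

  meth_path <- file.path(dir, "methylation.tsv")
  expr_path <- file.path(dir, "expression.tsv")
  grp_path <- file.path(dir, "grouping.tsv")
  truth_path <- file.path(dir, "truth.tsv")

  fmt <- function(m) formatC(m, format = "f", digits = 6)
  writeLines(c(paste(c("id", samples), collapse = "\t"),
               paste(keys, apply(fmt(betas), 1, paste, collapse = "\t"),
                     sep = "\t")), meth_path)
  writeLines(c(paste(c("gene", samples), collapse = "\t"),
               paste(paste0("GENE", seq_len(spec$n_genes)),
                     apply(fmt(expr), 1, paste, collapse = "\t"),
                     sep = "\t")), expr_path)
  writeLines(paste(samples, group_of, sep = "\t"), grp_path)
  writeLines(c("key\tgene\tsite_id\tplanted\tcoupled",
               paste(truth$key, truth$gene, truth$site_id,
                     ifelse(truth$planted, "TRUE", "FALSE"),
                     ifelse(truth$coupled, "TRUE", "FALSE"), sep = "\t")),
             truth_path)

  meth <- read_methylation_matrix(meth_path)
  list(methylation = meth,
       expression = read_expression_matrix(expr_path),
       grouping = read_grouping(grp_path, meth),
       truth = truth,
       paths = c(methylation = meth_path, expression = expr_path,
                 grouping = grp_path, truth = truth_path))
}
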