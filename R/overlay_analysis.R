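## Overlay analysis: match CpG sites / expression rows to pathway genes,
## apply the site-selection filters, aggregate per sample and per group,
## compute expression log2-fold values, mine similar patterns, screen
## methylation-expression correlation, and order samples for playback.

#' Site-selection filter specification
#'
#' Describes which CpG sites enter an analysis. A site passes when ALL
#' present criteria hold; with every field `NULL` every site passes.
#'
#' * `sd_threshold`: sample standard deviation of the site's non-missing
#'   betas (denominator n-1) must exceed this value. Sites with fewer than
#'   two non-missing betas fail any SD criterion.
#' * `beta_range`: `c(low, high)` in `[0,1]`; with `range_mode = "all"`
#'   every non-missing beta must fall inside, with `"any"` at least one.
#' * `locations`: subset of the Annovar region vocabulary the site's
#'   location must belong to.
#' * `site_list`: explicit set of probe ids / `chrom:pos` keys.
#'
#' @param sd_threshold Non-negative number or `NULL`.
#' @param beta_range Length-2 numeric in `[0,1]`, low <= high, or `NULL`.
#' @param locations Character vector or `NULL`.
#' @param site_list Character vector or `NULL`.
#' @param range_mode `"all"` (default) or `"any"`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(sd_threshold = NULL, beta_range = NULL,
                        locations = NULL, site_list = NULL,
                        range_mode = c("all", "any")) {
  range_mode <- match.arg(range_mode)
  if (!is.null(sd_threshold) &&
      (!is.numeric(sd_threshold) || sd_threshold < 0)) {
    stop("filter spec error: sd_threshold must be a non-negative number")
  }
  if (!is.null(beta_range)) {
    if (length(beta_range) != 2 || anyNA(beta_range) ||
        beta_range[1] > beta_range[2] ||
        beta_range[1] < 0 || beta_range[2] > 1) {
      stop("filter spec error: beta_range must be c(low, high) within [0,1] ",
           "with low <= high")
    }
  }
  structure(list(sd_threshold = sd_threshold, beta_range = beta_range,
                 locations = locations, site_list = site_list,
                 range_mode = range_mode),
            class = "filter_spec")
}

## Sample SD over non-missing values; NA when fewer than 2 observations.
site_sd <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) < 2) NA_real_ else stats::sd(v)
}

## Keys under which a site can be addressed in an explicit site list.
site_list_keys <- function(features, i) {
  keys <- features$site_id[i]
  if (!is.na(features$chrom[i]) && !is.na(features$pos[i])) {
    chrom <- features$chrom[i]
    bare <- sub("^chr", "", chrom)
    keys <- c(keys, paste0(chrom, ":", features$pos[i]),
              paste0("chr", bare, ":", features$pos[i]),
              paste0(bare, ":", features$pos[i]))
  }
  keys
}

#' Apply site-selection filters
#'
#' Partitions the rows of a methylation matrix (or a subset of them) into
#' passing and excluded sites under a [filter_spec()]. The two index sets
#' are disjoint and together cover the input, and the operation is
#' idempotent: re-filtering the passing set changes nothing.
#'
#' @param m An `omics_matrix` of kind `"methylation"`.
#' @param spec A [filter_spec()].
#' @param rows Integer row indices to consider (default all rows).
#' @return List with integer vectors `passing` and `excluded`.
#' @export
apply_filters <- function(m, spec = filter_spec(), rows = NULL) {
  stopifnot(inherits(m, "omics_matrix"), m$kind == "methylation",
            inherits(spec, "filter_spec"))
  if (is.null(rows)) rows <- seq_len(nrow(m$values))
  pass <- vapply(rows, function(i) site_passes(m, spec, i), logical(1))
  list(passing = rows[pass], excluded = rows[!pass])
}

## Single-site filter predicate (the per-criterion semantics live here).
site_passes <- function(m, spec, i) {
  v <- m$values[i, ]
  obs <- v[!is.na(v)]
  if (!is.null(spec$sd_threshold)) {
    s <- site_sd(v)
    if (is.na(s) || !(s > spec$sd_threshold)) return(FALSE)
  }
  if (!is.null(spec$beta_range)) {
    if (!length(obs)) return(FALSE)
    inside <- obs >= spec$beta_range[1] & obs <= spec$beta_range[2]
    ok <- if (spec$range_mode == "all") all(inside) else any(inside)
    if (!ok) return(FALSE)
  }
  if (!is.null(spec$locations)) {
    loc <- m$features$location[i]
    if (is.na(loc) ||
        !(tolower(loc) %in% tolower(spec$locations))) return(FALSE)
  }
  if (!is.null(spec$site_list)) {
    if (!any(site_list_keys(m$features, i) %in% spec$site_list)) return(FALSE)
  }
  ## a site with no observations can never pass an active filter,
  ## but passes the vacuous (empty) spec together with everything else
  TRUE
}

#' Match matrix rows to pathway gene entries
#'
#' A row matches a gene entry when its gene symbol equals any of the entry's
#' aliases, case-insensitively.
#'
#' @param graph A [pathway_graph()].
#' @param m An `omics_matrix` (methylation or expression).
#' @return Named list (by entry id) of lists with `label` and integer `rows`.
#' @export
match_sites <- function(graph, m) {
  genes_upper <- toupper(m$features$gene)
  out <- list()
  for (e in graph$entries) {
    if (e$entry_type != "gene") next
    rows <- which(genes_upper %in% toupper(e$aliases))
    out[[e$entry_id]] <- list(label = e$label, rows = rows)
  }
  out
}

#' Per-sample and per-group methylation display value of one gene
#'
#' The per-sample value is the mean beta over the gene's passing sites
#' (missing values skipped); the per-group value applies `aggregator` to the
#' group members' per-sample values. Samples or groups with no data get
#' `NA` — undefined is a value state, not an error.
#'
#' @param m Methylation `omics_matrix`.
#' @param rows Integer indices of the gene's passing sites.
#' @param grouping Optional `sample_grouping`.
#' @param aggregator `"mean"` (default) or `"median"` for the group value.
#' @return List with `per_sample` (named numeric over samples) and
#'   `per_group` (named numeric over groups, `NULL` without a grouping).
#' @export
gene_methylation_value <- function(m, rows, grouping = NULL,
                                   aggregator = c("mean", "median")) {
  aggregator <- match.arg(aggregator)
  agg <- if (aggregator == "mean") mean else stats::median
  per_sample <- colMeans(m$values[rows, , drop = FALSE], na.rm = TRUE)
  per_sample[is.nan(per_sample)] <- NA_real_
  per_group <- NULL
  if (!is.null(grouping)) {
    per_group <- vapply(
      stats::setNames(grouping$group_order, grouping$group_order),
      function(g) {
        v <- per_sample[names(grouping$assignment)[grouping$assignment == g]]
        v <- v[!is.na(v)]
        if (!length(v)) NA_real_ else agg(v)
      }, numeric(1))
  }
  list(per_sample = per_sample, per_group = per_group)
}

#' Clipped log2-fold expression value relative to the sample median
#'
#' `log2((value + eps) / (median(all_values) + eps))`, clipped to
#' `[-scale, +scale]`. The pseudocount guards against zero FPKM. A value
#' equal to the median maps to exactly 0.
#'
#' @param value FPKM value(s), vectorized.
#' @param all_values The gene's FPKM vector over all samples (missing
#'   skipped for the median).
#' @param scale Clip bound `s` (display scale), default 4.
#' @param pseudocount Pseudocount `eps` in FPKM units, default 0.01.
#' @return Numeric fold value(s) in `[-scale, scale]`; `NA` for missing
#'   input.
#' @export
expression_fold <- function(value, all_values, scale = 4, pseudocount = 0.01) {
  stopifnot(length(all_values) >= 1)
  med <- stats::median(all_values, na.rm = TRUE)
  f <- log2((value + pseudocount) / (med + pseudocount))
  pmin(pmax(f, -scale), scale)
}

## Root-mean-square (normalized = TRUE) or plain Euclidean distance between
## two per-sample vectors over their shared non-missing samples.
## NA when fewer than 2 shared observations.
pattern_distance <- function(a, b, normalized = TRUE) {
  keep <- !is.na(a) & !is.na(b)
  n <- sum(keep)
  if (n < 2) return(NA_real_)
  ss <- sum((a[keep] - b[keep])^2)
  if (normalized) sqrt(ss / n) else sqrt(ss)
}

#' Mine for genes with similar or dissimilar methylation/expression patterns
#'
#' The target pattern is the per-sample mean over the selected target rows.
#' Every row of the matrix (not restricted to any pathway) is a candidate;
#' distance is the root-mean-square difference over samples where both
#' vectors are non-missing, so rows with missing data remain comparable
#' (`normalized = FALSE` gives the plain Euclidean distance). Per gene only
#' the minimum-distance site is kept; the target's own gene is excluded;
#' candidates sharing fewer than two non-missing samples with the target are
#' skipped (logged). Hits are ranked by ascending distance for
#' `direction = "similar"`, descending for `"dissimilar"`, ties broken
#' lexicographically by gene symbol.
#'
#' @param m An `omics_matrix`.
#' @param target A gene symbol, or a character vector of site keys
#'   (site ids / row keys), or integer row indices.
#' @param top_k Number of hits to return.
#' @param direction `"similar"` or `"dissimilar"`.
#' @param normalized Use RMS distance (default) instead of plain Euclidean.
#' @return Data frame with `gene`, `site_id`, `distance`, `rank`.
#' @export
find_similar <- function(m, target, top_k = 10,
                         direction = c("similar", "dissimilar"),
                         normalized = TRUE) {
  direction <- match.arg(direction)
  if (is.numeric(target)) {
    t_rows <- as.integer(target)
  } else {
    t_rows <- which(toupper(m$features$gene) %in% toupper(target) |
                      m$features$site_id %in% target |
                      m$features$key %in% target)
  }
  if (!length(t_rows)) stop("target '", paste(target, collapse = ","),
                            "' matches no row of the matrix")
  tvec <- colMeans(m$values[t_rows, , drop = FALSE], na.rm = TRUE)
  tvec[is.nan(tvec)] <- NA_real_
  if (sum(!is.na(tvec)) < 2) {
    stop("target has fewer than two non-missing per-sample values")
  }
  t_genes <- unique(toupper(m$features$gene[t_rows]))
  cand <- which(!(toupper(m$features$gene) %in% t_genes) &
                  !is.na(m$features$gene))
  d <- vapply(cand, function(i)
    pattern_distance(tvec, m$values[i, ], normalized), numeric(1))
  skipped <- is.na(d)
  if (any(skipped)) {
    message("find_similar: skipped ", sum(skipped),
            " candidate site(s) with fewer than 2 shared samples")
  }
  cand <- cand[!skipped]; d <- d[!skipped]
  df <- data.frame(gene = m$features$gene[cand],
                   site_id = m$features$site_id[cand],
                   distance = d, stringsAsFactors = FALSE)
  ## per gene keep the best (minimum-distance) site
  df <- df[order(df$distance, df$gene, df$site_id), , drop = FALSE]
  df <- df[!duplicated(toupper(df$gene)), , drop = FALSE]
  if (direction == "similar") {
    df <- df[order(df$distance, df$gene), , drop = FALSE]
  } else {
    df <- df[order(-df$distance, df$gene), , drop = FALSE]
  }
  df <- utils::head(df, top_k)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Spearman correlation between a methylation and an expression vector
#'
#' Rank correlation with mean ranks for ties; the p-value uses the
#' t-distribution approximation with n-2 degrees of freedom. A constant
#' vector makes rho undefined (`NA`), reported as such rather than an
#' error.
#'
#' @param meth,expr Paired numeric vectors (matched samples); pairs with a
#'   missing value in either vector are dropped.
#' @return List with `rho`, `p_value`, `n` (pairs used) and `undefined`.
#' @export
methylation_expression_correlation <- function(meth, expr) {
  stopifnot(length(meth) == length(expr))
  keep <- !is.na(meth) & !is.na(expr)
  n <- sum(keep)
  if (n < 3) {
    stop("correlation requires at least 3 paired non-missing observations")
  }
  x <- meth[keep]; y <- expr[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, undefined = TRUE))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, undefined = FALSE)
}

#' Screen pathway genes for inverse methylation-expression correlation
#'
#' For every gene present in both matrices, correlates each of its (passing)
#' CpG sites with the gene's expression vector and keeps the site with the
#' most negative rho. A gene passes when that best rho is below `threshold`
#' (undefined correlations never pass). Optional Benjamini-Hochberg
#' adjustment adds a `p_adj` column; the pass decision stays on the rho
#' threshold as in plain screening.
#'
#' @param meth Methylation `omics_matrix`.
#' @param expr Expression `omics_matrix` (samples in the same order are
#'   matched by name).
#' @param threshold Rho threshold, default `-0.7`.
#' @param spec Optional [filter_spec()] restricting the sites considered.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame with `gene`, `site_id`, `rho`, `p_value`, `pass`
#'   (and `p_adj` when adjusted), sorted by ascending rho.
#' @export
correlation_screen <- function(meth, expr, threshold = -0.7,
                               spec = filter_spec(),
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  shared <- intersect(meth$samples, expr$samples)
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  keep_rows <- apply_filters(meth, spec)$passing
  genes <- intersect(unique(toupper(meth$features$gene[keep_rows])),
                     toupper(expr$features$gene))
  res <- list()
  for (g in sort(genes)) {
    e_row <- which(toupper(expr$features$gene) == g)[1]
    e_vec <- expr$values[e_row, shared]
    rows <- keep_rows[toupper(meth$features$gene[keep_rows]) == g]
    best <- NULL
    for (i in rows) {
      m_vec <- meth$values[i, shared]
      ok <- sum(!is.na(m_vec) & !is.na(e_vec)) >= 3
      if (!ok) next
      cc <- methylation_expression_correlation(m_vec, e_vec)
      if (cc$undefined) next
      if (is.null(best) || cc$rho < best$rho) {
        best <- list(site_id = meth$features$site_id[i], rho = cc$rho,
                     p_value = cc$p_value)
      }
    }
    if (!is.null(best)) {
      res[[length(res) + 1L]] <- data.frame(
        gene = meth$features$gene[rows[1]], site_id = best$site_id,
        rho = best$rho, p_value = best$p_value, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(gene = character(), site_id = character(),
                      rho = numeric(), p_value = numeric(),
                      pass = logical(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, res)
  if (adjust == "BH") df$p_adj <- stats::p.adjust(df$p_value, method = "BH")
  df$pass <- !is.na(df$rho) & df$rho < threshold
  df <- df[order(df$rho, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Order samples by the methylation of a key gene
#'
#' Sorts samples ascending by the gene's per-sample methylation value
#' (mean over passing sites); samples with an undefined value are placed
#' last, keeping their original relative order. Used to drive the playback
#' view, e.g. walking a cohort along the methylation of one caspase gene.
#'
#' @param m Methylation `omics_matrix`.
#' @param gene Gene symbol (case-insensitive).
#' @param spec Optional [filter_spec()].
#' @return Character vector of sample ids.
#' @export
order_samples <- function(m, gene, spec = filter_spec()) {
  rows <- which(toupper(m$features$gene) == toupper(gene))
  if (!length(rows)) stop("gene '", gene, "' not present in the matrix")
  passing <- apply_filters(m, spec, rows = rows)$passing
  if (!length(passing)) {
    stop("gene '", gene, "' has no site passing the filter")
  }
  vals <- gene_methylation_value(m, passing)$per_sample
  m$samples[order(vals, na.last = TRUE)]
}

#' Build per-gene overlays for a pathway
#'
#' The central assembly step: matches matrix rows to the pathway's gene
#' entries, applies the site filters (methylation), computes per-sample and
#' per-group display values, and flags each gene's status — `ok`,
#' `no_data` (no matching rows at all; rendered light green), or
#' `no_passing_sites` (sites exist but none passed the filter; rendered
#' gray). Genes backed by more than one passing site carry `multi_site`
#' (rendered with a green border).
#'
#' Methylation display values are beta means; expression display values are
#' clipped log2-fold changes versus the gene's median over all samples
#' ([expression_fold()]), with the group value computed from the group
#' members' median raw FPKM.
#'
#' @param graph A [pathway_graph()].
#' @param m An `omics_matrix`.
#' @param spec A [filter_spec()] (methylation only).
#' @param grouping Optional `sample_grouping`.
#' @param meth_aggregator Group aggregator for methylation, `"mean"`
#'   (default) or `"median"`.
#' @param fold_scale,pseudocount Passed to [expression_fold()].
#' @return A list of class `gene_overlays`; each element has `gene`,
#'   `entry_id`, `matched_rows`, `excluded_rows`, `per_sample_value`,
#'   `per_group_value`, `status`, `multi_site`. Attribute `kind` records
#'   the value scale.
#' @export
build_overlays <- function(graph, m, spec = filter_spec(), grouping = NULL,
                           meth_aggregator = c("mean", "median"),
                           fold_scale = 4, pseudocount = 0.01) {
  meth_aggregator <- match.arg(meth_aggregator)
  matches <- match_sites(graph, m)
  overlays <- list()
  for (id in names(matches)) {
    label <- matches[[id]]$label
    rows <- matches[[id]]$rows
    ov <- list(gene = label, entry_id = id, matched_rows = integer(),
               excluded_rows = integer(),
               per_sample_value = stats::setNames(
                 rep(NA_real_, length(m$samples)), m$samples),
               per_group_value = NULL, status = "no_data",
               multi_site = FALSE)
    if (length(rows)) {
      if (m$kind == "methylation") {
        part <- apply_filters(m, spec, rows = rows)
        ov$matched_rows <- part$passing
        ov$excluded_rows <- part$excluded
        if (!length(part$passing)) {
          ov$status <- "no_passing_sites"
        } else {
          ov$status <- "ok"
          ov$multi_site <- length(part$passing) > 1
          gv <- gene_methylation_value(m, part$passing, grouping,
                                       aggregator = meth_aggregator)
          ov$per_sample_value <- gv$per_sample
          ov$per_group_value <- gv$per_group
        }
      } else {
        ov$matched_rows <- rows
        ov$status <- "ok"
        ov$multi_site <- length(rows) > 1
        all_vals <- m$values[rows[1], ]
        ov$per_sample_value <- expression_fold(all_vals, all_vals,
                                               scale = fold_scale,
                                               pseudocount = pseudocount)
        if (!is.null(grouping)) {
          ov$per_group_value <- vapply(
            stats::setNames(grouping$group_order, grouping$group_order),
            function(g) {
              members <- names(grouping$assignment)[grouping$assignment == g]
              v <- all_vals[members]
              v <- v[!is.na(v)]
              if (!length(v)) return(NA_real_)
              expression_fold(stats::median(v), all_vals,
                              scale = fold_scale, pseudocount = pseudocount)
            }, numeric(1))
        }
      }
    }
    overlays[[length(overlays) + 1L]] <- ov
  }
  structure(overlays, class = "gene_overlays", kind = m$kind,
            fold_scale = fold_scale)
}
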