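## Metadata I/O: methylation / expression matrices, Bismark coverage,
## sample groupings, gene and site lists.
##
## Matrices are stored as an `omics_matrix`: a feature table (one row per
## CpG site or gene) plus a numeric value matrix with one column per sample.
## Methylation values are beta values in [0,1]; expression values are
## FPKM >= 0. Missing values are allowed everywhere ("NA" or empty cells).

LOCATION_VOCAB <- c("upstream", "downstream", "exonic", "intronic", "UTR5",
                    "UTR3", "splicing", "intergenic", "ncRNA")

new_omics_matrix <- function(kind, samples, features, values) {
  kind <- match.arg(kind, c("methylation", "expression"))
  stopifnot(is.matrix(values), ncol(values) == length(samples),
            nrow(values) == nrow(features))
  colnames(values) <- samples
  rownames(values) <- features$key
  structure(list(kind = kind, samples = samples, features = features,
                 values = values),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat("omics_matrix (", x$kind, "): ", nrow(x$values), " rows x ",
      length(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' Parse an underscore-annotated methylation row key
#'
#' Row keys carry the host gene symbol, optionally followed by
#' underscore-separated annotation tokens: a CpG probe id (`cg` + digits), a
#' genomic position (`chrN:pos`), and/or a genomic location category from the
#' Annovar region vocabulary (upstream, downstream, exonic, intronic, UTR5,
#' UTR3, splicing, intergenic, ncRNA; case-insensitive). Tokens matching none
#' of the patterns are folded back into the gene symbol, so gene names that
#' themselves contain underscores survive. The function is total: any
#' non-empty string parses.
#'
#' @param key Row key string, e.g. `"CASP8_cg05338167_exonic"`.
#' @return A list with `gene`, `site_id` (`NA` if absent), `chrom`, `pos`,
#'   `location`.
#' @examples
#' parse_annotated_key("CASP8_cg05338167_exonic")
#' parse_annotated_key("FAS_chr10:90750000_upstream")
#' @export
parse_annotated_key <- function(key) {
  stopifnot(is.character(key), length(key) == 1, nzchar(key))
  tokens <- strsplit(key, "_", fixed = TRUE)[[1]]
  gene <- tokens[1]
  site_id <- NA_character_
  chrom <- NA_character_
  pos <- NA_integer_
  location <- NA_character_
  for (tok in tokens[-1]) {
    if (is.na(site_id) && grepl("^cg[0-9]+$", tok)) {
      site_id <- tok
    } else if (is.na(chrom) && grepl("^(chr)?[A-Za-z0-9]+:[0-9]+$", tok)) {
      halves <- strsplit(tok, ":", fixed = TRUE)[[1]]
      chrom <- halves[1]
      pos <- as.integer(halves[2])
    } else if (is.na(location) &&
               tolower(tok) %in% tolower(c(LOCATION_VOCAB, "unknown"))) {
      location <- c(LOCATION_VOCAB, "unknown")[
        match(tolower(tok), tolower(c(LOCATION_VOCAB, "unknown")))]
    } else {
      gene <- paste(gene, tok, sep = "_")
    }
  }
  list(gene = gene, site_id = site_id, chrom = chrom, pos = pos,
       location = location)
}

#' Render site fields back into a canonical annotated key
#'
#' Inverse companion of [parse_annotated_key()]: fields are joined with
#' underscores in the fixed order gene, site id, position, location.
#'
#' @param gene Gene symbol.
#' @param site_id Probe id or `NA`.
#' @param chrom,pos Genomic position or `NA`.
#' @param location Location category or `NA`.
#' @return The composite key string.
#' @export
render_annotated_key <- function(gene, site_id = NA, chrom = NA, pos = NA,
                                 location = NA) {
  parts <- gene
  if (!is.na(site_id)) parts <- c(parts, site_id)
  if (!is.na(chrom) && !is.na(pos)) parts <- c(parts, paste0(chrom, ":", pos))
  if (!is.na(location)) parts <- c(parts, location)
  paste(parts, collapse = "_")
}

## Shared TSV-matrix reader: header row of sample ids, first column row keys.
## Returns list(keys, samples, values) with NA for "NA"/empty cells; any
## other non-numeric cell is an error naming the offending coordinates.
read_value_table <- function(source, what = "value") {
  lines <- readLines(source, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("validation error: empty input")
  rows <- strsplit(lines, "\t", fixed = TRUE)
  header <- rows[[1]]
  body <- rows[-1]
  n_fields <- length(rows[[if (length(body)) 2 else 1]])
  ## header may or may not name the key column
  samples <- if (length(header) == n_fields) header[-1] else header
  if (anyDuplicated(samples)) {
    stop("validation error: duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  keys <- character(length(body))
  values <- matrix(NA_real_, nrow = length(body), ncol = length(samples))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != length(samples) + 1L) {
      stop("validation error: row ", i + 1L, " has ", length(row),
           " fields, expected ", length(samples) + 1L)
    }
    keys[i] <- row[1]
    cells <- row[-1]
    missing <- tolower(cells) %in% c("na", "")
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(!missing & is.na(num))
    if (length(bad)) {
      stop("validation error: non-numeric ", what, " '", cells[bad[1]],
           "' at row '", keys[i], "', sample '", samples[bad[1]], "'")
    }
    num[missing] <- NA_real_
    values[i, ] <- num
  }
  list(keys = keys, samples = samples, values = values)
}

#' Read a methylation beta-value matrix
#'
#' Tab-separated input with a header row of sample ids and
#' annotated-gene-name row keys in the first column (see
#' [parse_annotated_key()]). Every non-missing cell must be a beta value in
#' `[0, 1]`; `"NA"` (case-insensitive) and empty cells are missing. Duplicate
#' composite row keys, and duplicate probe ids under the same gene, are
#' rejected.
#'
#' @param source File path or connection.
#' @return An `omics_matrix` of kind `"methylation"`.
#' @export
read_methylation_matrix <- function(source) {
  tab <- read_value_table(source, what = "beta value")
  out_of_range <- which(!is.na(tab$values) &
                          (tab$values < 0 | tab$values > 1), arr.ind = TRUE)
  if (nrow(out_of_range)) {
    i <- out_of_range[1, 1]; j <- out_of_range[1, 2]
    stop("validation error: beta value ", tab$values[i, j],
         " outside [0,1] at row '", tab$keys[i], "', sample '",
         tab$samples[j], "'")
  }
  parsed <- lapply(tab$keys, parse_annotated_key)
  features <- data.frame(
    key = tab$keys,
    gene = vapply(parsed, `[[`, character(1), "gene"),
    site_id = vapply(parsed, `[[`, character(1), "site_id"),
    chrom = vapply(parsed, `[[`, character(1), "chrom"),
    pos = vapply(parsed, `[[`, integer(1), "pos"),
    location = vapply(parsed, `[[`, character(1), "location"),
    stringsAsFactors = FALSE
  )
  ## auto-assign a site id for bare gene-name keys
  auto <- is.na(features$site_id)
  features$auto_id <- auto
  features$site_id[auto] <- features$key[auto]
  if (anyDuplicated(features$key)) {
    stop("validation error: duplicate row key '",
         features$key[duplicated(features$key)][1], "'")
  }
  pair <- paste(toupper(features$gene), features$site_id)
  if (anyDuplicated(pair)) {
    stop("validation error: duplicate site id '",
         features$site_id[duplicated(pair)][1], "' for gene '",
         features$gene[duplicated(pair)][1], "'")
  }
  new_omics_matrix("methylation", tab$samples, features, tab$values)
}

#' Read an FPKM expression matrix
#'
#' Tab-separated input with a header row of sample ids and bare gene-symbol
#' row keys. Values must be non-negative; missing allowed. Duplicate gene
#' rows are rejected.
#'
#' @param source File path or connection.
#' @return An `omics_matrix` of kind `"expression"`.
#' @export
read_expression_matrix <- function(source) {
  tab <- read_value_table(source, what = "FPKM value")
  neg <- which(!is.na(tab$values) & tab$values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    i <- neg[1, 1]; j <- neg[1, 2]
    stop("validation error: negative FPKM ", tab$values[i, j],
         " at gene '", tab$keys[i], "', sample '", tab$samples[j], "'")
  }
  if (anyDuplicated(toupper(tab$keys))) {
    stop("validation error: duplicate gene row '",
         tab$keys[duplicated(toupper(tab$keys))][1], "'")
  }
  features <- data.frame(key = tab$keys, gene = tab$keys,
                         stringsAsFactors = FALSE)
  new_omics_matrix("expression", tab$samples, features, tab$values)
}

#' Read Bismark coverage files into a methylation matrix
#'
#' Each input is a 6-column tab-separated Bismark `.cov` file (optionally
#' gzip-compressed): chromosome, start, end, methylation percentage, count
#' methylated, count unmethylated; coordinates are 1-based. Beta =
#' percentage / 100, keyed by `chrom:start`. Sites absent from one sample
#' are missing for that sample. Where both counts are nonzero and the
#' percentage disagrees with `meth/(meth+unmeth)` by more than 0.005 the
#' discrepancy is logged per site (message), not an error.
#'
#' @param sources Character vector of file paths, one per sample.
#' @param sample_ids Sample names, same length as `sources`.
#' @return An `omics_matrix` of kind `"methylation"` with genes unassigned
#'   (annotate with [annotate_matrix()]).
#' @export
read_bismark_coverage <- function(sources, sample_ids) {
  stopifnot(length(sources) == length(sample_ids),
            !anyDuplicated(sample_ids))
  per_sample <- vector("list", length(sources))
  for (k in seq_along(sources)) {
    tab <- utils::read.table(sources[k], sep = "\t", header = FALSE,
                             colClasses = "character")
    if (ncol(tab) != 6) {
      stop("validation error: '", sources[k], "' has ", ncol(tab),
           " columns, expected 6 (Bismark coverage format)")
    }
    pct <- as.numeric(tab[[4]])
    n_meth <- as.numeric(tab[[5]])
    n_unmeth <- as.numeric(tab[[6]])
    if (anyNA(pct) || any(pct < 0 | pct > 100)) {
      stop("validation error: methylation percentage outside [0,100] in '",
           sources[k], "'")
    }
    if (anyNA(n_meth) || anyNA(n_unmeth) || any(n_meth < 0 | n_unmeth < 0)) {
      stop("validation error: negative or non-numeric counts in '",
           sources[k], "'")
    }
    key <- paste0(tab[[1]], ":", tab[[2]])
    both <- n_meth > 0 & n_unmeth > 0
    ratio <- n_meth / (n_meth + n_unmeth)
    off <- both & abs(pct / 100 - ratio) > 0.005
    if (any(off)) {
      message("bismark: ", sum(off), " site(s) in sample '", sample_ids[k],
              "' where the percentage column disagrees with the counts ",
              "beyond 0.005 (first: ", key[which(off)[1]], ")")
    }
    per_sample[[k]] <- data.frame(key = key, chrom = tab[[1]],
                                  pos = as.integer(tab[[2]]),
                                  beta = pct / 100, stringsAsFactors = FALSE)
  }
  all_keys <- unique(unlist(lapply(per_sample, `[[`, "key")))
  values <- matrix(NA_real_, nrow = length(all_keys),
                   ncol = length(sample_ids))
  for (k in seq_along(per_sample)) {
    idx <- match(per_sample[[k]]$key, all_keys)
    values[idx, k] <- per_sample[[k]]$beta
  }
  first <- do.call(rbind, per_sample)
  first <- first[!duplicated(first$key), , drop = FALSE]
  first <- first[match(all_keys, first$key), , drop = FALSE]
  features <- data.frame(key = all_keys, gene = NA_character_,
                         site_id = all_keys, chrom = first$chrom,
                         pos = first$pos, location = NA_character_,
                         auto_id = FALSE, stringsAsFactors = FALSE)
  new_omics_matrix("methylation", sample_ids, features, values)
}

#' Read a sample grouping table
#'
#' Two tab-separated columns without a header: sample id, group label.
#' Group order follows first appearance in the file. Samples present in the
#' matrix but absent from the file are assigned to an implicit `"unknown"`
#' group placed last; samples in the file but not in the matrix produce a
#' warning and are ignored. Conflicting duplicate assignments are an error.
#'
#' @param source File path or connection, or `NULL`/missing file content for
#'   an all-unknown grouping.
#' @param matrix An `omics_matrix` whose samples the grouping applies to.
#' @return A list of class `sample_grouping` with `assignment` (named
#'   character, one entry per matrix sample) and `group_order`.
#' @export
read_grouping <- function(source, matrix) {
  lines <- if (is.null(source)) character() else readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ids <- character(); labels <- character()
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- vapply(parts, `[`, character(1), 1)
    labels <- vapply(parts, function(p) if (length(p) > 1) p[2] else "unknown",
                     character(1))
    dup <- duplicated(ids)
    if (any(dup)) {
      for (d in unique(ids[dup])) {
        if (length(unique(labels[ids == d])) > 1) {
          stop("validation error: sample '", d,
               "' assigned to conflicting groups")
        }
      }
      labels <- labels[!dup]
      ids <- ids[!dup]
    }
    extra <- setdiff(ids, matrix$samples)
    if (length(extra)) {
      warning("grouping lists ", length(extra),
              " sample(s) not present in the matrix: ",
              paste(utils::head(extra, 3), collapse = ", "))
      keep <- ids %in% matrix$samples
      ids <- ids[keep]; labels <- labels[keep]
    }
  }
  assignment <- stats::setNames(rep("unknown", length(matrix$samples)),
                                matrix$samples)
  assignment[ids] <- labels
  group_order <- unique(labels)
  if (any(assignment == "unknown") && !("unknown" %in% group_order)) {
    group_order <- c(group_order, "unknown")
  }
  structure(list(assignment = assignment, group_order = group_order),
            class = "sample_grouping")
}

#' Group sizes in display order
#' @param grouping A `sample_grouping`.
#' @return Named integer vector, one count per group in `group_order`.
#' @export
group_sizes <- function(grouping) {
  vapply(stats::setNames(grouping$group_order, grouping$group_order),
         function(g) sum(grouping$assignment == g), integer(1))
}

#' Read a pre-selected CpG site list
#'
#' One entry (probe id or genomic position) per line; blank lines and lines
#' starting with `#` are ignored; duplicates are removed.
#'
#' @param source File path or connection.
#' @return Character vector of unique site keys.
#' @export
read_site_list <- function(source) {
  lines <- trimws(readLines(source, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Read a plain gene list
#'
#' Same format as [read_site_list()] but interpreted as gene symbols.
#'
#' @inheritParams read_site_list
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(source) read_site_list(source)

#' Write an omics matrix as TSV
#'
#' Fixture/round-trip writer: emits the header row of sample ids and one row
#' per feature. Methylation row keys are re-rendered through
#' [render_annotated_key()] (auto-assigned site ids are omitted so that a
#' written matrix re-reads equal). Values are printed with 6 decimals;
#' missing cells as `NA`.
#'
#' @param m An `omics_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(m, path) {
  if (m$kind == "methylation") {
    f <- m$features
    keys <- vapply(seq_len(nrow(f)), function(i) {
      render_annotated_key(f$gene[i],
                           site_id = if (isTRUE(f$auto_id[i])) NA
                                     else f$site_id[i],
                           chrom = f$chrom[i], pos = f$pos[i],
                           location = f$location[i])
    }, character(1))
  } else {
    keys <- m$features$gene
  }
  fmt <- ifelse(is.na(m$values), "NA",
                formatC(m$values, format = "f", digits = 6))
  lines <- c(paste(c("id", m$samples), collapse = "\t"),
             paste(keys, apply(fmt, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

## Equality helper used by round-trip tests.
omics_equal <- function(a, b, tolerance = 1e-9) {
  isTRUE(all.equal(a$samples, b$samples)) &&
    identical(a$kind, b$kind) &&
    isTRUE(all.equal(a$features$gene, b$features$gene)) &&
    isTRUE(all.equal(unname(a$values), unname(b$values),
                     tolerance = tolerance))
}
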