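## Site annotation: replace CpG probe ids / genomic positions with annotated
## gene names, producing the underscore-joined row keys the overlay expects.
## The annotation itself (probe -> gene, location) is an input table in the
## style of an Annovar region annotation; this module only applies it.

#' Read a probe/position-to-gene annotation table
#'
#' Four tab-separated columns with a header: `key` (probe id or genomic
#' position), `key_type` (`probe` or `position`), `gene`, `location`
#' (Annovar region category or empty). Position keys are normalized to
#' `chrN:pos`. One key may map to several genes — one row per gene.
#'
#' @param source File path or connection.
#' @return A data frame of class `annotation_table`.
#' @export
read_annotation_table <- function(source) {
  tab <- utils::read.table(source, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  need <- c("key", "key_type", "gene", "location")
  if (!all(need %in% names(tab))) {
    stop("validation error: annotation table must have columns ",
         paste(need, collapse = ", "))
  }
  bad <- !(tab$key_type %in% c("probe", "position"))
  if (any(bad)) {
    stop("validation error: unknown key_type '", tab$key_type[bad][1], "'")
  }
  pos <- tab$key_type == "position"
  tab$key[pos] <- ifelse(grepl("^chr", tab$key[pos]), tab$key[pos],
                         paste0("chr", tab$key[pos]))
  tab$location[!nzchar(tab$location)] <- NA_character_
  known <- is.na(tab$location) |
    tolower(tab$location) %in% tolower(LOCATION_VOCAB)
  tab$location[!known] <- "unknown"
  structure(tab, class = c("annotation_table", "data.frame"))
}

## Normalize a matrix row's lookup key to match the table index.
annotation_lookup_key <- function(features, i) {
  if (grepl("^cg[0-9]+$", features$site_id[i])) {
    features$site_id[i]
  } else if (!is.na(features$chrom[i]) && !is.na(features$pos[i])) {
    chrom <- features$chrom[i]
    if (!grepl("^chr", chrom)) chrom <- paste0("chr", chrom)
    paste0(chrom, ":", features$pos[i])
  } else {
    features$site_id[i]
  }
}

#' Annotate a probe- or position-keyed methylation matrix with gene names
#'
#' Re-keys each row of a methylation matrix whose rows are identified by
#' Illumina probe id or genomic position. Matched rows receive the composite
#' key `gene[_siteid][_position][_location]` (fields selected by `include`,
#' order fixed so [parse_annotated_key()] round-trips); rows with no table
#' match are dropped and counted; a key annotated to k genes fans out to k
#' rows sharing the identical beta vector. Row order of survivors is
#' preserved.
#'
#' @param m An `omics_matrix` of kind `"methylation"` keyed by probe id or
#'   position.
#' @param table An [read_annotation_table()] result (or a data frame with the
#'   same columns).
#' @param include Character subset of `c("site_id", "position", "location")`
#'   selecting which fields join the gene name in the new key.
#' @return The re-keyed `omics_matrix`; attributes `dropped` (row count with
#'   no annotation) and `fanout_extra` (extra rows created by multi-gene
#'   probes) record the conversion.
#' @export
annotate_matrix <- function(m, table,
                            include = c("site_id", "location")) {
  stopifnot(inherits(m, "omics_matrix"), m$kind == "methylation")
  if (!nrow(table)) stop("validation error: empty annotation table")
  include <- match.arg(include, c("site_id", "position", "location"),
                       several.ok = TRUE)
  idx_rows <- list(); idx_feats <- list()
  dropped <- 0L; extra <- 0L
  for (i in seq_len(nrow(m$features))) {
    key <- annotation_lookup_key(m$features, i)
    hits <- which(table$key == key)
    if (!length(hits)) {
      dropped <- dropped + 1L
      next
    }
    extra <- extra + length(hits) - 1L
    for (h in hits) {
      site_id <- if ("site_id" %in% include && grepl("^cg", key)) key
                 else NA_character_
      chrom <- NA_character_; pos <- NA_integer_
      if ("position" %in% include && grepl(":", key, fixed = TRUE)) {
        halves <- strsplit(key, ":", fixed = TRUE)[[1]]
        chrom <- halves[1]; pos <- as.integer(halves[2])
      }
      location <- if ("location" %in% include) table$location[h]
                  else NA_character_
      new_key <- render_annotated_key(table$gene[h], site_id = site_id,
                                      chrom = chrom, pos = pos,
                                      location = location)
      idx_rows[[length(idx_rows) + 1L]] <- i
      idx_feats[[length(idx_feats) + 1L]] <- data.frame(
        key = new_key, gene = table$gene[h],
        site_id = if (is.na(site_id)) key else site_id,
        chrom = chrom, pos = pos, location = location, auto_id = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  features <- if (length(idx_feats)) do.call(rbind, idx_feats) else
    data.frame(key = character(), gene = character(), site_id = character(),
               chrom = character(), pos = integer(), location = character(),
               auto_id = logical(), stringsAsFactors = FALSE)
  values <- m$values[unlist(idx_rows), , drop = FALSE]
  if (anyDuplicated(features$key)) {
    stop("validation error: annotation produced duplicate row key '",
         features$key[duplicated(features$key)][1], "'")
  }
  out <- new_omics_matrix("methylation", m$samples, features, values)
  attr(out, "dropped") <- dropped
  attr(out, "fanout_extra") <- extra
  out
}

#' Summarize an annotation conversion
#'
#' Computed from the two matrices alone: `dropped` counts input rows whose
#' site key no longer appears in the output, `fanout_extra` the additional
#' rows created by multi-gene annotations, so that
#' `rows_in = dropped + rows_out - fanout_extra`.
#'
#' @param before Matrix passed to [annotate_matrix()].
#' @param after Its result.
#' @return A list with `rows_in`, `rows_out`, `dropped`, `fanout_extra`.
#' @export
annotation_report <- function(before, after) {
  stopifnot(identical(before$samples, after$samples))
  in_keys <- vapply(seq_len(nrow(before$features)),
                    function(i) annotation_lookup_key(before$features, i),
                    character(1))
  kept <- in_keys %in% after$features$site_id
  rows_in <- nrow(before$features)
  rows_out <- nrow(after$features)
  dropped <- sum(!kept)
  list(rows_in = rows_in, rows_out = rows_out, dropped = dropped,
       fanout_extra = rows_out - (rows_in - dropped))
}
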