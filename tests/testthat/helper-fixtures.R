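# Hand-built KGML fixture: 3 gene entries, 1 map entry, 2 relations
# (activation, inhibition). Entry 2 carries a multi-symbol graphics name
# with a trailing ellipsis, as KEGG emits.
fixture_kgml <- function() {
  paste0(
    '<?xml version="1.0"?>\n',
    '<pathway name="path:hsa99999" org="hsa" title="fixture pathway">\n',
    '  <entry id="10" name="hsa:836" type="gene">\n',
    '    <graphics name="CASP3, CPP32" type="rectangle" x="100" y="60"',
    ' width="46" height="17"/>\n',
    '  </entry>\n',
    '  <entry id="11" name="hsa:2064" type="gene">\n',
    '    <graphics name="ERBB2, HER-2, ..." type="rectangle" x="220" y="60"',
    ' width="46" height="17"/>\n',
    '  </entry>\n',
    '  <entry id="12" name="hsa:355" type="gene">\n',
    '    <graphics name="FAS" type="rectangle" x="160" y="140"',
    ' width="46" height="17"/>\n',
    '  </entry>\n',
    '  <entry id="13" name="path:hsa04210" type="map">\n',
    '    <graphics name="Apoptosis" type="roundrectangle" x="160" y="220"',
    ' width="80" height="25"/>\n',
    '  </entry>\n',
    '  <relation entry1="10" entry2="11" type="PPrel">\n',
    '    <subtype name="activation" value="--&gt;"/>\n',
    '  </relation>\n',
    '  <relation entry1="11" entry2="12" type="PPrel">\n',
    '    <subtype name="inhibition" value="--|"/>\n',
    '  </relation>\n',
    '</pathway>\n')
}

# Build a small methylation matrix in memory by writing and re-reading a
# TSV so every test exercises the real reader.
fixture_meth_matrix <- function(keys, values, samples) {
  stopifnot(nrow(values) == length(keys), ncol(values) == length(samples))
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  fmt <- ifelse(is.na(values), "NA",
                formatC(values, format = "f", digits = 6))
  writeLines(c(paste(c("id", samples), collapse = "\t"),
               paste(keys, apply(fmt, 1, paste, collapse = "\t"),
                     sep = "\t")), path)
  read_methylation_matrix(path)
}

fixture_expr_matrix <- function(genes, values, samples) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  fmt <- ifelse(is.na(values), "NA",
                formatC(values, format = "f", digits = 6))
  writeLines(c(paste(c("gene", samples), collapse = "\t"),
               paste(genes, apply(fmt, 1, paste, collapse = "\t"),
                     sep = "\t")), path)
  read_expression_matrix(path)
}

# Independent brute-force oracles ------------------------------------------

# RMS / Euclidean distance over pairwise-complete samples, written
# independently of pattern_distance().
oracle_distance <- function(a, b, normalized = TRUE) {
  keep <- which(!is.na(a) & !is.na(b))
  if (length(keep) < 2) return(NA_real_)
  total <- 0
  for (i in keep) total <- total + (a[i] - b[i])^2
  if (normalized) sqrt(total / length(keep)) else sqrt(total)
}

# Per-site filter decision re-implemented naively for the oracle test.
oracle_site_pass <- function(betas, location, site_keys, spec) {
  obs <- betas[!is.na(betas)]
  if (!is.null(spec$sd_threshold)) {
    if (length(obs) < 2) return(FALSE)
    m <- sum(obs) / length(obs)
    s <- sqrt(sum((obs - m)^2) / (length(obs) - 1))
    if (!(s > spec$sd_threshold)) return(FALSE)
  }
  if (!is.null(spec$beta_range)) {
    if (length(obs) == 0) return(FALSE)
    inside <- obs >= spec$beta_range[1] & obs <= spec$beta_range[2]
    if (spec$range_mode == "all" && !all(inside)) return(FALSE)
    if (spec$range_mode == "any" && !any(inside)) return(FALSE)
  }
  if (!is.null(spec$locations)) {
    if (is.na(location)) return(FALSE)
    if (!(tolower(location) %in% tolower(spec$locations))) return(FALSE)
  }
  if (!is.null(spec$site_list)) {
    if (!any(site_keys %in% spec$site_list)) return(FALSE)
  }
  TRUE
}
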