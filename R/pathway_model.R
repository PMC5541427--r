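#' @keywords internal
"_PACKAGE"

## Pathway model: typed KGML pathway graphs.
##
## A pathway graph is an ordered collection of entries (gene, compound, map,
## group ... nodes with pixel-space graphics boxes) and typed relations
## between them, as encoded in KEGG Markup Language (KGML).

ENTRY_TYPES <- c("gene", "ortholog", "compound", "map", "group", "enzyme", "other")
RELATION_CLASSES <- c("PPrel", "GErel", "ECrel", "PCrel", "maplink")
RELATION_SUBTYPES <- c("activation", "inhibition", "repression", "expression",
                       "methylation", "phosphorylation", "indirect", "binding",
                       "unknown")
GRAPHICS_SHAPES <- c("rectangle", "circle", "roundrectangle", "line")

#' Construct a pathway graph
#'
#' Builds the in-memory pathway representation used throughout the package:
#' an ordered list of entry nodes (each with a graphics box whose `x`/`y`
#' are the KGML box *center*) and an ordered list of typed relation edges.
#' Invariants are checked: entry ids must be unique and every relation
#' endpoint must reference an existing entry.
#'
#' @param pathway_id KEGG pathway identifier, e.g. `"hsa04668"`.
#' @param organism KEGG organism code (2-4 letters).
#' @param title Human-readable pathway title.
#' @param entries List of entry nodes as produced by [pathway_entry()].
#' @param relations List of relation edges as produced by [pathway_relation()].
#' @return An object of class `methpath_pathway`.
#' @seealso [parse_kgml()], [serialize_graph()]
#' @export
pathway_graph <- function(pathway_id, organism, title = "", entries = list(),
                          relations = list()) {
  ids <- vapply(entries, function(e) e$entry_id, character(1))
  if (anyDuplicated(ids)) {
    stop("schema error: duplicate entry ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (r in relations) {
    if (!(r$source_entry %in% ids) || !(r$target_entry %in% ids)) {
      stop("schema error: relation endpoint '",
           setdiff(c(r$source_entry, r$target_entry), ids)[1],
           "' does not reference an existing entry")
    }
  }
  structure(
    list(pathway_id = pathway_id, organism = organism, title = title,
         entries = entries, relations = relations),
    class = "methpath_pathway"
  )
}

#' Construct one pathway entry node
#'
#' @param entry_id Entry identifier (unique within a graph).
#' @param entry_type One of gene, ortholog, compound, map, group, enzyme, other.
#' @param kegg_ids Character vector of KEGG accessions (e.g. `"hsa:2064"`).
#' @param label Display gene symbol (first comma-separated token of the KGML
#'   graphics name, trailing ellipsis stripped).
#' @param aliases All comma-separated graphics-name tokens; must contain
#'   `label`.
#' @param graphics List with `x`, `y` (box center), `width`, `height`,
#'   `shape`.
#' @param components For group entries, the component entry ids.
#' @return A list of class `methpath_entry`.
#' @export
pathway_entry <- function(entry_id, entry_type, kegg_ids = character(),
                          label = "", aliases = character(),
                          graphics = list(x = 0, y = 0, width = 46,
                                          height = 17, shape = "rectangle"),
                          components = character()) {
  entry_type <- match.arg(entry_type, ENTRY_TYPES)
  if (entry_type == "gene" && !nzchar(label)) {
    stop("schema error: gene entry '", entry_id, "' has an empty label")
  }
  if (nzchar(label) && !(label %in% aliases)) aliases <- c(label, aliases)
  graphics$shape <- match.arg(graphics$shape, GRAPHICS_SHAPES)
  if (graphics$shape == "rectangle" &&
      (graphics$width <= 0 || graphics$height <= 0)) {
    stop("schema error: rectangle graphics of entry '", entry_id,
         "' must have positive width and height")
  }
  structure(
    list(entry_id = as.character(entry_id), entry_type = entry_type,
         kegg_ids = as.character(kegg_ids), label = label,
         aliases = as.character(aliases), graphics = graphics,
         components = as.character(components)),
    class = "methpath_entry"
  )
}

#' Construct one typed relation edge
#'
#' @param source_entry,target_entry Entry ids of the endpoints.
#' @param relation_class KGML relation type (PPrel, GErel, ECrel, PCrel,
#'   maplink).
#' @param subtypes Character vector of interaction subtypes; names outside the
#'   recognized vocabulary are mapped to `"unknown"`, and an empty set is
#'   treated as unknown at render time.
#' @return A list of class `methpath_relation`.
#' @export
pathway_relation <- function(source_entry, target_entry,
                             relation_class = "PPrel",
                             subtypes = character()) {
  relation_class <- match.arg(relation_class, RELATION_CLASSES)
  subtypes <- unique(ifelse(subtypes %in% RELATION_SUBTYPES, subtypes, "unknown"))
  structure(
    list(source_entry = as.character(source_entry),
         target_entry = as.character(target_entry),
         relation_class = relation_class,
         subtypes = as.character(subtypes)),
    class = "methpath_relation"
  )
}

## Split a KGML graphics name attribute into display label + alias set.
## KEGG packs several symbols into one attribute: "ERBB2, HER-2, ...".
split_graphics_name <- function(name) {
  tokens <- trimws(strsplit(name, ",", fixed = TRUE)[[1]])
  tokens <- sub("\\.\\.\\.$", "", tokens)
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  list(label = if (length(tokens)) tokens[1] else "", aliases = tokens)
}

#' Parse a KGML pathway document
#'
#' Reads KEGG Markup Language XML into a typed pathway graph. Entries and
#' relations preserve document order; relation subtype names outside the
#' recognized vocabulary are retained as `"unknown"` rather than dropped;
#' group entries retain their component entry ids. Graphics `x`/`y` follow
#' the KGML convention of box centers.
#'
#' @param source A file path, URL, raw vector, or XML string accepted by
#'   [xml2::read_xml()].
#' @return A [pathway_graph()] object.
#' @examples
#' kgml <- make_kgml(n_genes = 4, n_relations = 2, seed = 1)
#' g <- parse_kgml(kgml)
#' length(g$entries)
#' @export
parse_kgml <- function(source) {
  doc <- tryCatch(
    xml2::read_xml(source),
    error = function(e) stop("KGML parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  root <- xml2::xml_name(doc)
  if (!identical(root, "pathway")) {
    stop("KGML schema error: root element is <", root, ">, expected <pathway>")
  }
  pid <- sub("^path:", "", xml2::xml_attr(doc, "name", default = ""))
  org <- xml2::xml_attr(doc, "org", default = "")
  title <- xml2::xml_attr(doc, "title", default = "")

  entries <- lapply(xml2::xml_find_all(doc, "./entry"), function(node) {
    id <- xml2::xml_attr(node, "id")
    if (is.na(id) || !nzchar(id)) {
      stop("KGML schema error: <entry> element without an id attribute")
    }
    type <- xml2::xml_attr(node, "type", default = "other")
    if (!(type %in% ENTRY_TYPES)) type <- "other"
    kegg_ids <- strsplit(xml2::xml_attr(node, "name", default = ""), " ",
                         fixed = TRUE)[[1]]
    kegg_ids <- kegg_ids[nzchar(kegg_ids)]
    gnode <- xml2::xml_find_first(node, "./graphics")
    gname <- ""
    graphics <- list(x = 0, y = 0, width = 46, height = 17,
                     shape = "rectangle")
    if (!inherits(gnode, "xml_missing")) {
      gname <- xml2::xml_attr(gnode, "name", default = "")
      if (is.na(gname)) gname <- ""
      shape <- xml2::xml_attr(gnode, "type", default = "rectangle")
      if (!(shape %in% GRAPHICS_SHAPES)) shape <- "rectangle"
      num_attr <- function(a, default) {
        v <- suppressWarnings(as.numeric(xml2::xml_attr(gnode, a)))
        if (is.na(v)) default else v
      }
      graphics <- list(x = num_attr("x", 0), y = num_attr("y", 0),
                       width = num_attr("width", 46),
                       height = num_attr("height", 17), shape = shape)
    }
    nm <- split_graphics_name(gname)
    label <- nm$label
    if (type == "gene" && !nzchar(label)) {
      label <- if (length(kegg_ids)) kegg_ids[1] else id
      nm$aliases <- c(label, nm$aliases)
    }
    components <- xml2::xml_attr(xml2::xml_find_all(node, "./component"), "id")
    pathway_entry(id, type, kegg_ids = kegg_ids, label = label,
                  aliases = nm$aliases, graphics = graphics,
                  components = components)
  })

  relations <- lapply(xml2::xml_find_all(doc, "./relation"), function(node) {
    cls <- xml2::xml_attr(node, "type", default = "PPrel")
    if (!(cls %in% RELATION_CLASSES)) cls <- "PPrel"
    subtypes <- xml2::xml_attr(xml2::xml_find_all(node, "./subtype"), "name")
    pathway_relation(xml2::xml_attr(node, "entry1"),
                     xml2::xml_attr(node, "entry2"),
                     relation_class = cls, subtypes = subtypes)
  })

  pathway_graph(pid, org, title, entries, relations)
}

## Canonical KGML arrow glyph per subtype (value attribute of <subtype>).
SUBTYPE_VALUES <- c(activation = "-->", inhibition = "--|", repression = "--|",
                    expression = "-->", methylation = "+m",
                    phosphorylation = "+p", indirect = "..>", binding = "---",
                    unknown = "---")

#' Serialize a pathway graph back to KGML
#'
#' Inverse of [parse_kgml()]: `parse_kgml(serialize_graph(g))` is
#' structurally equal to `g`. Output is byte-deterministic for a fixed graph.
#'
#' @param graph A [pathway_graph()] object.
#' @return A raw vector holding the KGML XML bytes.
#' @export
serialize_graph <- function(graph) {
  if (!inherits(graph, "methpath_pathway")) {
    stop("serialization error: not a pathway graph")
  }
  ## re-validate invariants (errors if an edited graph went stale)
  graph <- pathway_graph(graph$pathway_id, graph$organism, graph$title,
                         graph$entries, graph$relations)
  doc <- xml2::xml_new_root("pathway",
                            name = paste0("path:", graph$pathway_id),
                            org = graph$organism,
                            title = graph$title)
  for (e in graph$entries) {
    node <- xml2::xml_add_child(doc, "entry", id = e$entry_id,
                                name = paste(e$kegg_ids, collapse = " "),
                                type = e$entry_type)
    xml2::xml_add_child(node, "graphics",
                        name = paste(e$aliases, collapse = ", "),
                        type = e$graphics$shape,
                        x = format(e$graphics$x), y = format(e$graphics$y),
                        width = format(e$graphics$width),
                        height = format(e$graphics$height))
    for (comp in e$components) {
      xml2::xml_add_child(node, "component", id = comp)
    }
  }
  for (r in graph$relations) {
    node <- xml2::xml_add_child(doc, "relation", entry1 = r$source_entry,
                                entry2 = r$target_entry,
                                type = r$relation_class)
    for (s in r$subtypes) {
      xml2::xml_add_child(node, "subtype", name = s,
                          value = SUBTYPE_VALUES[[s]])
    }
  }
  charToRaw(as.character(doc))
}

#' Structural equality of two pathway graphs
#'
#' Compares pathway id, organism, title, and the ordered entry and relation
#' collections field by field (subtype order-insensitive).
#'
#' @param a,b Pathway graphs.
#' @return `TRUE` or `FALSE`.
#' @export
graphs_equal <- function(a, b) {
  norm <- function(g) {
    list(
      id = g$pathway_id, org = g$organism, title = g$title,
      entries = lapply(g$entries, function(e) {
        e$graphics <- lapply(e$graphics, function(v)
          if (is.numeric(v)) as.numeric(v) else v)
        unclass(e)
      }),
      relations = lapply(g$relations, function(r) {
        r$subtypes <- sort(r$subtypes)
        unclass(r)
      })
    )
  }
  isTRUE(all.equal(norm(a), norm(b), tolerance = 1e-9))
}

## ---- KEGG REST access (injectable transport, local cache) ----

kegg_rest_base <- "https://rest.kegg.jp"

## Default transport: GET a URL, return the response body as a raw vector.
## Replaced by a local function in tests so nothing touches the network.
http_get_raw <- function(url) {
  con <- base::url(url, open = "rb")
  on.exit(close(con))
  chunks <- list()
  repeat {
    b <- readBin(con, what = "raw", n = 65536L)
    if (!length(b)) break
    chunks[[length(chunks) + 1L]] <- b
  }
  do.call(c, c(chunks, list(raw(0))))
}

#' Fetch (and cache) a KEGG pathway as a parsed graph
#'
#' Downloads the KGML document for `pathway_id` from the KEGG REST API the
#' first time, stores it byte-identical in `cache_dir`, and parses the cached
#' copy on every call. With `offline = TRUE` a cache miss is an error instead
#' of a download.
#'
#' @param pathway_id KEGG pathway id matching `^[a-z]{2,4}[0-9]{5}$`.
#' @param cache_dir Directory for cached KGML files (created if absent).
#' @param offline If `TRUE`, never touch the network.
#' @param transport Function `function(url) raw_bytes` performing the HTTP
#'   GET; injectable so tests can serve fixtures locally.
#' @return A [pathway_graph()] object.
#' @export
fetch_pathway <- function(pathway_id, cache_dir, offline = FALSE,
                          transport = http_get_raw) {
  if (!grepl("^[a-z]{2,4}[0-9]{5}$", pathway_id)) {
    stop("invalid pathway id '", pathway_id,
         "': expected an organism code followed by five digits")
  }
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  cache_file <- file.path(cache_dir, paste0(pathway_id, ".kgml"))
  if (!file.exists(cache_file)) {
    if (offline) {
      stop("cache-miss error: no cached KGML for '", pathway_id,
           "' in offline mode")
    }
    bytes <- tryCatch(
      transport(paste0(kegg_rest_base, "/get/", pathway_id, "/kgml")),
      error = function(e) stop("fetch error for '", pathway_id, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    writeBin(bytes, cache_file)
  }
  parse_kgml(cache_file)
}

#' List the pathways available for an organism
#'
#' Queries the KEGG `list/pathway/<organism>` endpoint (tab-separated
#' `id<TAB>title` lines, with an optional `path:` prefix on ids) and caches
#' the response per organism in `cache_dir`.
#'
#' @inheritParams fetch_pathway
#' @param organism KEGG organism code, e.g. `"hsa"`.
#' @return A data frame with columns `pathway_id` and `title`, in server
#'   order.
#' @export
list_pathways <- function(organism, cache_dir, offline = FALSE,
                          transport = http_get_raw) {
  if (!grepl("^[a-z]{2,4}$", organism)) {
    stop("invalid organism code '", organism, "'")
  }
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  cache_file <- file.path(cache_dir, paste0("pathway_list_", organism, ".tsv"))
  if (!file.exists(cache_file)) {
    if (offline) {
      stop("cache-miss error: no cached pathway list for '", organism,
           "' in offline mode")
    }
    bytes <- tryCatch(
      transport(paste0(kegg_rest_base, "/list/pathway/", organism)),
      error = function(e) stop("fetch error for pathway list '", organism,
                               "': ", conditionMessage(e), call. = FALSE)
    )
    writeBin(bytes, cache_file)
  }
  lines <- readLines(cache_file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(pathway_id = character(), title = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    pathway_id = vapply(parts, function(p) sub("^path:", "", p[1]),
                        character(1)),
    title = vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                   character(1)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.methpath_pathway <- function(x, ...) {
  cat("KEGG pathway graph '", x$pathway_id, "' (", x$organism, "): ",
      x$title, "\n  ", length(x$entries), " entries, ",
      length(x$relations), " relations\n", sep = "")
  invisible(x)
}
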