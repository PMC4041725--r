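#' Read a Petri net model file
#'
#' Supported dialects: standard PNML place/transition nets; a plain tabular
#' net format (see [write_net()] for the layout); and, read-only, the
#' Snoopy-style XML dialect used by hierarchical pathway models (`.spped`).
#' The Snoopy reader first looks for the expected node classes (`Place`,
#' `Transition`, `Coarse Transition`, logical flags) and falls back to a
#' generic scan for place-like / transition-like / edge-like elements,
#' reporting what it matched. Hierarchy (coarse transitions), logical-node
#' flags and the initial marking are preserved; arc weights default to 1
#' when a file omits them.
#'
#' @param path path to the model file.
#' @param format `"auto"` (sniff from content/extension), `"pnml"`,
#'   `"spped"` or `"tabular"`.
#' @return a list of class `net_document`: `net` (a [petri_net()]),
#'   `source_format`, `metadata`.
#' @export
read_net <- function(path, format = c("auto", "pnml", "spped", "tabular")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    head1 <- paste(readLines(path, n = 5, warn = FALSE), collapse = " ")
    format <- if (grepl("<", head1, fixed = TRUE)) {
      doc <- xml2::read_xml(path)
      root <- xml2::xml_name(doc)
      if (tolower(root) == "pnml") "pnml"
      else if (tolower(root) %in% c("snoopy", "spped")) "spped"
      else stop("unknown XML dialect; root element <", root, ">")
    } else "tabular"
  }
  net <- switch(format,
                pnml = read_pnml(path),
                spped = read_spped(path),
                tabular = read_tabular(path))
  structure(list(net = net$net, source_format = format,
                 metadata = net$metadata),
            class = "net_document")
}

#' @export
print.net_document <- function(x, ...) {
  cat("<net_document> format ", x$source_format, "\n", sep = "")
  print(x$net)
  invisible(x)
}

#' Write a Petri net model file
#'
#' The tabular dialect has three sections, each introduced by a bracketed
#' section line and a tab-separated header: `[PLACES]` (id, name, tokens,
#' logical), `[TRANSITIONS]` (id, name, kind, parent), `[ARCS]` (source,
#' target, weight, read_pair). PNML output conforms to the standard
#' place/transition net schema; hierarchy and logical flags are not
#' representable there, so PNML is written for flat nets (flatten first).
#' The Snoopy dialect is read-only.
#'
#' @param doc a `net_document` or a plain [petri_net()].
#' @param path output path.
#' @param format `"tabular"` or `"pnml"`.
#' @return invisibly, `path`.
#' @export
write_net <- function(doc, path, format = c("tabular", "pnml", "spped")) {
  format <- match.arg(format)
  net <- if (inherits(doc, "net_document")) doc$net else doc
  stopifnot(inherits(net, "petri_net"))
  if (format == "spped") stop("write not supported for spped (read-only dialect)")
  if (format == "tabular") write_tabular(net, path) else write_pnml(net, path)
  invisible(path)
}

## ---------------------------------------------------------------- tabular

write_tabular <- function(net, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  p <- net$places; t <- net$transitions; a <- net$arcs
  writeLines("[PLACES]", con)
  writeLines(paste("id", "name", "tokens", "logical", sep = "\t"), con)
  writeLines(paste(p$id, p$name, p$tokens, as.integer(p$is_logical),
                   sep = "\t"), con)
  writeLines("[TRANSITIONS]", con)
  writeLines(paste("id", "name", "kind", "parent", sep = "\t"), con)
  writeLines(paste(t$id, t$name, t$kind,
                   ifelse(is.na(t$parent), "-", t$parent), sep = "\t"), con)
  writeLines("[ARCS]", con)
  writeLines(paste("source", "target", "weight", "read_pair", sep = "\t"), con)
  if (nrow(a) > 0) {
    writeLines(paste(a$source, a$target, a$weight, as.integer(a$read),
                     sep = "\t"), con)
  }
}

read_tabular <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sec_at <- grep("^\\[(PLACES|TRANSITIONS|ARCS)\\]$", lines)
  if (length(sec_at) != 3) stop("tabular net file needs the three sections ",
                                "[PLACES], [TRANSITIONS], [ARCS]")
  names(sec_at) <- gsub("[\\[\\]]", "", lines[sec_at], perl = TRUE)
  bounds <- c(sec_at, length(lines) + 1)
  grab <- function(section) {
    i <- which(names(sec_at) == section)
    body <- lines[(bounds[i] + 1):(bounds[i + 1] - 1)]
    if (length(body) < 1) stop("empty section ", section)
    con <- textConnection(body)
    on.exit(close(con))
    utils::read.delim(con, header = TRUE, stringsAsFactors = FALSE,
                      colClasses = "character")
  }
  p <- grab("PLACES"); t <- grab("TRANSITIONS"); a <- grab("ARCS")
  places <- data.frame(id = p$id, name = p$name,
                       is_logical = p$logical == "1",
                       tokens = as.integer(p$tokens))
  transitions <- data.frame(id = t$id, name = t$name, kind = t$kind,
                            parent = ifelse(t$parent == "-", NA_character_,
                                            t$parent))
  arcs <- if (nrow(a) > 0) {
    data.frame(source = a$source, target = a$target,
               weight = as.integer(a$weight), read = a$read_pair == "1")
  } else data.frame(source = character(), target = character(),
                    weight = integer(), read = logical())
  list(net = petri_net(places, transitions, arcs,
                       name = sub("\\.[^.]*$", "", basename(path))),
       metadata = list(tool = "tabular"))
}

## ------------------------------------------------------------------ PNML

write_pnml <- function(net, path) {
  stop_if_not_flat(net, "write_net(format = 'pnml')")
  doc <- xml2::xml_new_root("pnml",
                            xmlns = "http://www.pnml.org/version-2009/grammar/pnml")
  netn <- xml2::xml_add_child(doc, "net", id = net$name,
                              type = "http://www.pnml.org/version-2009/grammar/ptnet")
  page <- xml2::xml_add_child(netn, "page", id = "page0")
  for (i in seq_len(nrow(net$places))) {
    pl <- xml2::xml_add_child(page, "place", id = net$places$id[i])
    nm <- xml2::xml_add_child(pl, "name")
    xml2::xml_add_child(nm, "text", net$places$name[i])
    if (net$places$tokens[i] > 0) {
      mk <- xml2::xml_add_child(pl, "initialMarking")
      xml2::xml_add_child(mk, "text", as.character(net$places$tokens[i]))
    }
  }
  for (i in seq_len(nrow(net$transitions))) {
    tr <- xml2::xml_add_child(page, "transition", id = net$transitions$id[i])
    nm <- xml2::xml_add_child(tr, "name")
    xml2::xml_add_child(nm, "text", net$transitions$name[i])
  }
  for (i in seq_len(nrow(net$arcs))) {
    ar <- xml2::xml_add_child(page, "arc", id = sprintf("a%d", i),
                              source = net$arcs$source[i],
                              target = net$arcs$target[i])
    if (net$arcs$weight[i] != 1) {
      ins <- xml2::xml_add_child(ar, "inscription")
      xml2::xml_add_child(ins, "text", as.character(net$arcs$weight[i]))
    }
  }
  xml2::write_xml(doc, path)
}

read_pnml <- function(path) {
  doc <- xml2::read_xml(path)
  if (tolower(xml2::xml_name(doc)) != "pnml") {
    stop("not a PNML document; root element <", xml2::xml_name(doc), ">")
  }
  xml2::xml_ns_strip(doc)
  netn <- xml2::xml_find_first(doc, ".//net")
  net_id <- xml2::xml_attr(netn, "id")
  if (is.na(net_id)) net_id <- "pnml_net"
  text_of <- function(node, xpath) {
    v <- xml2::xml_text(xml2::xml_find_first(node, xpath))
    if (length(v) == 0) NA_character_ else v
  }
  pl_nodes <- xml2::xml_find_all(doc, ".//place")
  places <- data.frame(
    id = xml2::xml_attr(pl_nodes, "id"),
    name = vapply(pl_nodes, text_of, "", "./name/text"),
    tokens = vapply(pl_nodes, function(n) {
      v <- text_of(n, "./initialMarking/text")
      if (is.na(v)) 0L else as.integer(v)
    }, integer(1))
  )
  places$name[is.na(places$name)] <- places$id[is.na(places$name)]
  tr_nodes <- xml2::xml_find_all(doc, ".//transition")
  transitions <- data.frame(
    id = xml2::xml_attr(tr_nodes, "id"),
    name = vapply(tr_nodes, text_of, "", "./name/text")
  )
  transitions$name[is.na(transitions$name)] <-
    transitions$id[is.na(transitions$name)]
  arc_nodes <- xml2::xml_find_all(doc, ".//arc")
  arcs <- data.frame(
    source = xml2::xml_attr(arc_nodes, "source"),
    target = xml2::xml_attr(arc_nodes, "target"),
    weight = vapply(arc_nodes, function(n) {
      v <- text_of(n, "./inscription/text")
      if (is.na(v)) 1L else as.integer(v)
    }, integer(1)),
    read = FALSE
  )
  if (nrow(arcs) != length(arc_nodes)) stop("arc parse mismatch")
  arcs <- detect_read_pairs(arcs)
  ## boundary kinds are structural in PNML: no pre-places => input, etc.
  kind <- rep("internal", nrow(transitions))
  has_pre <- transitions$id %in% arcs$target
  has_post <- transitions$id %in% arcs$source
  kind[!has_pre & has_post] <- "input"
  kind[has_pre & !has_post] <- "output"
  transitions$kind <- kind
  list(net = petri_net(places, transitions, arcs, name = net_id),
       metadata = list(tool = "pnml"))
}

## mark matched opposite arcs of equal weight between the same node pair
detect_read_pairs <- function(arcs) {
  if (nrow(arcs) == 0) return(arcs)
  fwd <- paste(arcs$source, arcs$target, arcs$weight)
  rev <- paste(arcs$target, arcs$source, arcs$weight)
  arcs$read <- fwd %in% rev
  arcs
}

## ----------------------------------------------------------------- spped

read_spped <- function(path) {
  doc <- xml2::read_xml(path)
  root <- tolower(xml2::xml_name(doc))
  if (!(root %in% c("snoopy", "spped"))) {
    stop("not a Snoopy document; root element <", xml2::xml_name(doc), ">")
  }
  xml2::xml_ns_strip(doc)
  ncs <- xml2::xml_find_all(doc, ".//nodeclass")
  nodes_of <- function(pattern) {
    sel <- ncs[grepl(pattern, tolower(xml2::xml_attr(ncs, "name")))]
    do.call(rbind, lapply(sel, function(nc) {
      nn <- xml2::xml_find_all(nc, "./node")
      if (length(nn) == 0) return(NULL)
      data.frame(
        id = xml2::xml_attr(nn, "id"),
        name = vapply(nn, spped_attr, "", "Name"),
        marking = vapply(nn, spped_attr, "", "Marking"),
        logic = vapply(nn, spped_attr, "", "Logic"),
        class = xml2::xml_attr(nc, "name")
      )
    }))
  }
  pl <- nodes_of("place")
  tr_plain <- nodes_of("^transition$|^transition ")
  tr_coarse <- nodes_of("coarse")
  used_generic <- FALSE
  if (is.null(pl) || is.null(tr_plain)) {
    ## generic fallback: scan for any place-like / transition-like /
    ## edge-like elements by local name
    used_generic <- TRUE
    pl_nodes <- xml2::xml_find_all(doc, ".//*[contains(translate(name(), 'PLACE', 'place'), 'place')]")
    tr_nodes <- xml2::xml_find_all(doc, ".//*[contains(translate(name(), 'TRANSIO', 'transio'), 'transition')]")
    message("spped generic-XML fallback: matched ", length(pl_nodes),
            " place-like and ", length(tr_nodes), " transition-like elements")
    pl <- data.frame(id = xml2::xml_attr(pl_nodes, "id"),
                     name = xml2::xml_attr(pl_nodes, "name"),
                     marking = xml2::xml_attr(pl_nodes, "marking"),
                     logic = NA_character_, class = "Place")
    tr_plain <- data.frame(id = xml2::xml_attr(tr_nodes, "id"),
                           name = xml2::xml_attr(tr_nodes, "name"),
                           marking = NA, logic = NA, class = "Transition")
    tr_coarse <- NULL
  }
  edges <- xml2::xml_find_all(doc, ".//edge")
  if (length(edges) == 0) edges <- xml2::xml_find_all(doc, ".//arc")
  a <- data.frame(
    source = xml2::xml_attr(edges, "source"),
    target = xml2::xml_attr(edges, "target"),
    weight = vapply(edges, function(e) {
      w <- spped_attr(e, "Multiplicity")
      if (is.na(w) || !nzchar(w)) w <- xml2::xml_attr(e, "multiplicity")
      if (is.na(w) || !nzchar(w)) 1L else as.integer(w)
    }, integer(1)),
    read = FALSE
  )
  tr <- rbind(
    if (!is.null(tr_plain))
      data.frame(id = tr_plain$id, name = tr_plain$name, kind = "internal",
                 parent = NA_character_),
    if (!is.null(tr_coarse))
      data.frame(id = tr_coarse$id, name = tr_coarse$name, kind = "macro",
                 parent = NA_character_)
  )
  ## coarse membership, when recorded as an attribute on the child
  places <- data.frame(
    id = pl$id,
    name = ifelse(is.na(pl$name) | !nzchar(pl$name), pl$id, pl$name),
    is_logical = grepl("logic", tolower(pl$class)) |
      (!is.na(pl$logic) & pl$logic %in% c("1", "true")),
    tokens = ifelse(is.na(pl$marking) | !nzchar(pl$marking), 0L,
                    suppressWarnings(as.integer(pl$marking)))
  )
  places$tokens[is.na(places$tokens)] <- 0L
  tr$name <- ifelse(is.na(tr$name) | !nzchar(tr$name), tr$id, tr$name)
  a <- detect_read_pairs(a)
  dangling <- setdiff(c(a$source, a$target), c(places$id, tr$id))
  if (length(dangling) > 0) {
    stop("dangling arc endpoint(s) in spped file: ",
         paste(utils::head(dangling, 5), collapse = ", "))
  }
  ## boundary kinds from structure
  has_pre <- tr$id %in% a$target
  has_post <- tr$id %in% a$source
  tr$kind[tr$kind == "internal" & !has_pre & has_post] <- "input"
  tr$kind[tr$kind == "internal" & has_pre & !has_post] <- "output"
  list(net = petri_net(places, tr, a,
                       name = sub("\\.[^.]*$", "", basename(path))),
       metadata = list(tool = "snoopy", generic_fallback = used_generic))
}

## Snoopy stores node attributes as <attribute name="..."> children whose
## text (or nested text node) carries the value.
spped_attr <- function(node, attr_name) {
  a <- xml2::xml_find_first(node,
                            sprintf("./attribute[@name='%s']", attr_name))
  if (inherits(a, "xml_missing")) return(NA_character_)
  trimws(xml2::xml_text(a))
}
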