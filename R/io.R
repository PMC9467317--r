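#' Write a Petri net as PNML
#'
#' Emits the ISO/IEC 15909-2 core model: `<place>` with `<initialMarking>`,
#' `<transition>`, and `<arc>` with `<inscription>` weights. Read-arc pairs
#' are written as two opposite arcs carrying a `<toolspecific>` read flag;
#' logical-copy and annotation attributes travel the same way so a write/read
#' round trip reproduces an isomorphic net.
#'
#' @param net a `petri_net`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pnml <- function(net, path) {
  doc <- xml2::xml_new_root("pnml", xmlns = "http://www.pnml.org/version-2009/grammar/pnml")
  nn <- xml2::xml_add_child(doc, "net", id = "net1",
                            type = "http://www.pnml.org/version-2009/grammar/ptnet")
  pg <- xml2::xml_add_child(nn, "page", id = "page1")
  for (i in seq_len(nrow(net$places))) {
    p <- net$places[i, ]
    pn <- xml2::xml_add_child(pg, "place", id = p$id)
    xml2::xml_add_child(xml2::xml_add_child(pn, "name"), "text", p$name)
    if (net$marking[[p$id]] > 0) {
      xml2::xml_add_child(xml2::xml_add_child(pn, "initialMarking"), "text",
                          format(net$marking[[p$id]]))
    }
    if (!is.na(p$annotation) || isTRUE(p$logical_copy)) {
      ts <- xml2::xml_add_child(pn, "toolspecific", tool = "pnpath", version = "1")
      if (!is.na(p$annotation)) xml2::xml_set_attr(ts, "annotation", p$annotation)
      if (isTRUE(p$logical_copy)) xml2::xml_set_attr(ts, "logical", "true")
    }
  }
  for (i in seq_len(nrow(net$transitions))) {
    tr <- net$transitions[i, ]
    tn <- xml2::xml_add_child(pg, "transition", id = tr$id)
    xml2::xml_add_child(xml2::xml_add_child(tn, "name"), "text", tr$name)
  }
  for (i in seq_len(nrow(net$arcs))) {
    a <- net$arcs[i, ]
    an <- xml2::xml_add_child(pg, "arc", id = sprintf("a%d", i),
                              source = a$source, target = a$target)
    if (a$weight != 1) {
      xml2::xml_add_child(xml2::xml_add_child(an, "inscription"), "text",
                          format(a$weight))
    }
    if (a$read) {
      xml2::xml_add_child(an, "toolspecific", tool = "pnpath", version = "1",
                          read = "true")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a Petri net from PNML
#'
#' Parses the PNML core model. Places whose name carries a logical-copy flag
#' (or duplicated place names when `merge_logical = TRUE`) are merged into a
#' single vertex, mirroring how layout tools duplicate heavily connected
#' places.
#'
#' @param path PNML file
#' @param merge_logical merge logical place copies after reading
#' @param strict error on conflicting annotations among merged copies
#' @return a `petri_net`
#' @export
read_pnml <- function(path, merge_logical = TRUE, strict = FALSE) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pnodes <- xml2::xml_find_all(doc, ".//place")
  places <- data.frame(
    id = xml2::xml_attr(pnodes, "id"),
    name = vapply(pnodes, function(n) {
      t <- xml2::xml_find_first(n, "./name/text")
      if (inherits(t, "xml_missing")) xml2::xml_attr(n, "id") else xml2::xml_text(t)
    }, character(1)),
    annotation = vapply(pnodes, function(n)
      xml2::xml_attr(xml2::xml_find_first(n, "./toolspecific"), "annotation"),
      character(1)),
    logical_copy = vapply(pnodes, function(n)
      identical(xml2::xml_attr(xml2::xml_find_first(n, "./toolspecific"), "logical"),
                "true"), logical(1))
  )
  marking <- vapply(pnodes, function(n) {
    t <- xml2::xml_find_first(n, "./initialMarking/text")
    if (inherits(t, "xml_missing")) 0 else as.numeric(xml2::xml_text(t))
  }, numeric(1))
  names(marking) <- places$id

  tnodes <- xml2::xml_find_all(doc, ".//transition")
  transitions <- data.frame(
    id = xml2::xml_attr(tnodes, "id"),
    name = vapply(tnodes, function(n) {
      t <- xml2::xml_find_first(n, "./name/text")
      if (inherits(t, "xml_missing")) xml2::xml_attr(n, "id") else xml2::xml_text(t)
    }, character(1))
  )

  anodes <- xml2::xml_find_all(doc, ".//arc")
  arcs <- data.frame(
    source = xml2::xml_attr(anodes, "source"),
    target = xml2::xml_attr(anodes, "target"),
    weight = vapply(anodes, function(n) {
      t <- xml2::xml_find_first(n, "./inscription/text")
      if (inherits(t, "xml_missing")) 1 else as.numeric(xml2::xml_text(t))
    }, numeric(1)),
    read = vapply(anodes, function(n)
      identical(xml2::xml_attr(xml2::xml_find_first(n, "./toolspecific"), "read"),
                "true"), logical(1))
  )
  net <- petri_net(places, transitions, arcs, marking = marking[marking > 0])
  if (merge_logical && any(places$logical_copy)) {
    net <- merge_logical_places(net, strict = strict)
  }
  net
}

#' Read a Petri net from a MonaLisa-style SBML export
#'
#' Qualitative Petri-net tools export P/T nets as plain SBML: species are
#' places (initial amounts give the marking), reactions are transitions
#' (stoichiometries give arc weights), and a reactant that is also a product
#' with equal stoichiometry encodes a read arc. The dialect is autodetected
#' by the presence of `listOfSpecies`/`listOfReactions` without kinetic laws
#' being required.
#'
#' @param path SBML file
#' @return a `petri_net`
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp) == 0L) .stopf("no species found; not a Petri-net SBML export")
  places <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name"))
  )
  amount <- suppressWarnings(as.numeric(xml2::xml_attr(sp, "initialAmount")))
  amount[is.na(amount)] <- 0
  names(amount) <- places$id

  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  transitions <- data.frame(
    id = xml2::xml_attr(rx, "id"),
    name = ifelse(is.na(xml2::xml_attr(rx, "name")),
                  xml2::xml_attr(rx, "id"), xml2::xml_attr(rx, "name"))
  )
  arcs <- list()
  for (r in rx) {
    rid <- xml2::xml_attr(r, "id")
    sref <- function(xp) {
      nodes <- xml2::xml_find_all(r, xp)
      if (length(nodes) == 0L) return(NULL)
      w <- suppressWarnings(as.numeric(xml2::xml_attr(nodes, "stoichiometry")))
      w[is.na(w)] <- 1
      data.frame(species = xml2::xml_attr(nodes, "species"), weight = w)
    }
    reac <- sref("./listOfReactants/speciesReference")
    prod <- sref("./listOfProducts/speciesReference")
    both <- intersect(reac$species, prod$species)
    for (s in both) {
      wr <- reac$weight[reac$species == s]
      wp <- prod$weight[prod$species == s]
      if (wr == wp) {  # read arc
        arcs[[length(arcs) + 1L]] <- data.frame(
          source = c(s, rid), target = c(rid, s), weight = wr, read = TRUE)
        reac <- reac[reac$species != s, , drop = FALSE]
        prod <- prod[prod$species != s, , drop = FALSE]
      }
    }
    if (!is.null(reac) && nrow(reac)) {
      arcs[[length(arcs) + 1L]] <- data.frame(
        source = reac$species, target = rid, weight = reac$weight, read = FALSE)
    }
    if (!is.null(prod) && nrow(prod)) {
      arcs[[length(arcs) + 1L]] <- data.frame(
        source = rid, target = prod$species, weight = prod$weight, read = FALSE)
    }
  }
  petri_net(places, transitions, do.call(rbind, arcs),
            marking = amount[amount > 0])
}
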