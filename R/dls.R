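## ---------------------------------------------------------------------------
## DLS evolutionary scenarios: bracket grammar, validation, gene-tree
## extraction, and direct episode scoring of explicit scenario sets
## ---------------------------------------------------------------------------

## Flat DLS representation: per node `kind` in {gene, loss, dup, spec},
## `children`, `label` (gene leaves), `species` (sorted species set).

new_dls <- function(kind, children, label, species, root) {
  n <- length(kind)
  parent <- rep(NA_integer_, n)
  for (v in seq_len(n)) for (k in children[[v]]) parent[k] <- v
  structure(list(n = n, kind = kind, children = children, parent = parent,
                 label = label, species = species, root = root),
            class = "me_dls")
}

flatten_dls <- function(nested) {
  kind <- character(0); children <- list(); label <- character(0)
  species <- list()
  rec <- function(node) {
    kids <- integer(0)
    if (node$kind %in% c("dup", "spec"))
      kids <- vapply(node$kids, rec, 0L)
    kind[[length(kind) + 1L]] <<- node$kind
    children[[length(children) + 1L]] <<- kids
    label[[length(label) + 1L]] <<-
      if (node$kind == "gene") node$label else NA_character_
    species[[length(species) + 1L]] <<- switch(
      node$kind,
      gene = node$label,
      loss = sort(node$species),
      sort(unique(unlist(species[kids]))))
    length(kind)
  }
  root <- rec(nested)
  new_dls(kind, children, label, species, root)
}

validate_dls <- function(T) {
  for (v in seq_len(T$n)) {
    kids <- T$children[[v]]
    if (T$kind[v] == "dup") {
      if (!identical(T$species[[kids[1]]], T$species[[kids[2]]]))
        stop("duplication children carry unequal species sets: {",
             paste(T$species[[kids[1]]], collapse = ","), "} vs {",
             paste(T$species[[kids[2]]], collapse = ","), "}")
    } else if (T$kind[v] == "spec") {
      if (length(intersect(T$species[[kids[1]]], T$species[[kids[2]]])))
        stop("speciation children carry overlapping species sets")
    } else if (T$kind[v] == "loss") {
      if (!length(T$species[[v]])) stop("loss leaf with empty species set")
    }
  }
  invisible(T)
}

#' Parse a DLS scenario string
#'
#' Grammar: a species name is a gene-sequence leaf; a species-set token
#' followed by `-` is a loss leaf; `(X,Y)+` is a duplication (children must
#' carry equal species sets) and `(X,Y)~` a speciation (children must carry
#' disjoint sets).  Both the ASCII tilde and the Unicode similarity sign are
#' accepted for speciations.  With `loss_delim = ""` a loss token such as
#' `ab-` is read as the set of its characters; a non-empty delimiter supports
#' multi-character species names.
#'
#' @param text the scenario string (optional trailing `;` ignored).
#' @param loss_delim delimiter inside loss-leaf species-set tokens.
#' @return an object of class `me_dls`.
#' @examples
#' T <- parse_dls("(((((a,a)+,b-)~,(c,d-)~)~,(ab-,(c-,d)~)~)+,e)~")
#' mes_of_scenarios(list(T), parse_newick("(((a,b),(c,d)),e);", "species"))
#' @export
parse_dls <- function(text, loss_delim = "") {
  s <- gsub("∼", "~", trimws(text))
  s <- sub(";$", "", s)
  pos <- 1L
  peek <- function() if (pos <= nchar(s)) substr(s, pos, pos) else ""
  advance <- function() pos <<- pos + 1L
  expect <- function(ch) {
    if (peek() != ch) stop("DLS parse error at position ", pos,
                           ": expected '", ch, "', found '", peek(), "'")
    advance()
  }
  read_name <- function() {
    start <- pos
    while (grepl("^[A-Za-z0-9_.|]$", peek())) advance()
    if (pos == start) stop("DLS parse error at position ", pos,
                           ": expected a name")
    substr(s, start, pos - 1L)
  }
  rec <- function() {
    if (peek() == "(") {
      advance()
      left <- rec()
      expect(",")
      right <- rec()
      expect(")")
      ev <- peek()
      if (ev == "+") { advance(); return(list(kind = "dup", kids = list(left, right))) }
      if (ev == "~") { advance(); return(list(kind = "spec", kids = list(left, right))) }
      stop("DLS parse error at position ", pos,
           ": expected '+' or '~' after ')'")
    }
    nm <- read_name()
    if (peek() == "-") {
      advance()
      set <- if (nzchar(loss_delim)) strsplit(nm, loss_delim, fixed = TRUE)[[1]]
             else strsplit(nm, "")[[1]]
      return(list(kind = "loss", species = set))
    }
    list(kind = "gene", label = nm)
  }
  out <- rec()
  if (pos <= nchar(s)) stop("DLS parse error: trailing text at position ", pos)
  validate_dls(flatten_dls(out))
}

#' Write a DLS scenario string
#' @param T an `me_dls` scenario.
#' @param loss_delim delimiter for loss-leaf species-set tokens.
#' @param spec_sym symbol emitted for speciation nodes (`"~"` by default).
#' @return the scenario string.
#' @export
write_dls <- function(T, loss_delim = "", spec_sym = "~") {
  rec <- function(v) {
    switch(T$kind[v],
           gene = T$label[v],
           loss = paste0(paste(T$species[[v]], collapse = loss_delim), "-"),
           dup = paste0("(", rec(T$children[[v]][1]), ",",
                        rec(T$children[[v]][2]), ")+"),
           spec = paste0("(", rec(T$children[[v]][1]), ",",
                         rec(T$children[[v]][2]), ")", spec_sym))
  }
  rec(T$root)
}

#' @export
print.me_dls <- function(x, ...) {
  cat(sprintf("DLS scenario: %d gene(s), %d loss(es), %d duplication(s)\n  %s\n",
              sum(x$kind == "gene"), sum(x$kind == "loss"),
              sum(x$kind == "dup"), write_dls(x)))
  invisible(x)
}

#' Extract the gene tree of a DLS scenario
#'
#' Takes the smallest subgraph of the scenario containing all gene-sequence
#' leaves and contracts nodes of degree 2, yielding the rooted gene tree the
#' scenario explains.
#'
#' @param T an `me_dls` scenario with at least one gene leaf.
#' @return a rooted gene tree.
#' @export
gt <- function(T) {
  if (!sum(T$kind == "gene")) stop("scenario contains no gene sequences")
  rec <- function(v) {
    if (T$kind[v] == "gene") return(list(kind = "leaf", label = T$species[[v]]))
    if (T$kind[v] == "loss") return(NULL)
    kids <- Filter(Negate(is.null), lapply(T$children[[v]], rec))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1]])
    list(kind = "node", kids = kids)
  }
  nested <- rec(T$root)
  # flatten into the rooted gene tree representation (postorder ids)
  parent <- integer(0); children <- list(); label <- character(0)
  build <- function(node) {
    kids <- if (node$kind == "node")
      vapply(node$kids, build, 0L) else integer(0)
    children[[length(children) + 1L]] <<- kids
    label[[length(label) + 1L]] <<-
      if (node$kind == "leaf") node$label else NA_character_
    length(children)
  }
  root <- build(nested)
  n <- length(children)
  parent <- rep(NA_integer_, n)
  for (v in seq_len(n)) for (k in children[[v]]) parent[k] <- v
  new_rooted_tree(parent, children, label, root)
}

#' Is a scenario compatible with a species tree?
#'
#' Compatibility requires every node's species set to occur as a cluster of
#' the species tree.
#'
#' @param T an `me_dls` scenario.
#' @param S a species tree.
#' @return logical.
#' @export
dls_compatible <- function(T, S) {
  clusters <- vapply(S$cluster, paste, "", collapse = ",")
  all(vapply(T$species, paste, "", collapse = ",") %in% clusters)
}

## Longest comparable-duplication chain per cluster within one scenario.
duppath_by_cluster <- function(T) {
  best <- new.env(parent = emptyenv())
  depth <- new.env(parent = emptyenv())
  rec <- function(v) {
    key <- NULL
    if (T$kind[v] == "dup") {
      key <- paste(T$species[[v]], collapse = ",")
      cur <- if (is.null(depth[[key]])) 1L else depth[[key]] + 1L
      depth[[key]] <- cur
      if (is.null(best[[key]]) || cur > best[[key]]) best[[key]] <- cur
    }
    for (k in T$children[[v]]) rec(k)
    if (!is.null(key)) depth[[key]] <- depth[[key]] - 1L
  }
  rec(T$root)
  out <- unlist(as.list(best))
  if (is.null(out)) stats::setNames(integer(0), character(0)) else out
}

#' Episode score of an explicit scenario set
#'
#' Sums, over the species-tree nodes, the maximum over scenarios of the
#' longest chain of comparable duplication nodes whose cluster equals that
#' node's cluster.  This is the episode count of the best clustering of the
#' given scenarios: duplications with one cluster share an episode unless
#' they are comparable within one scenario.
#'
#' @param R list of `me_dls` scenarios, all compatible with `S`.
#' @param S a species tree.
#' @return integer episode count.
#' @export
mes_of_scenarios <- function(R, S) {
  paths <- lapply(R, function(T) {
    if (!dls_compatible(T, S))
      stop("scenario incompatible with the species tree")
    duppath_by_cluster(T)
  })
  total <- 0L
  for (v in seq_len(S$n)) {
    key <- paste(S$cluster[[v]], collapse = ",")
    m <- max(c(0L, vapply(paths, function(p)
      if (key %in% names(p)) p[[key]] else 0L, 0L)))
    total <- total + m
  }
  total
}
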