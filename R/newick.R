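# Newick and extended-Newick parsing --------------------------------------
#
# A small recursive-descent parser shared by parseNewick() and
# parseExtendedNewick().  The extended dialect is exactly the three-field
# colon syntax "length:support:gamma", with a single hybrid node tagged
# "#H<id>" that appears twice (once defining its subtree, once as a
# reference); the middle (support) field is ignored.  Plain parsing
# reports the 1-based character position of any syntax error.

.nwkError <- function(pos, msg) {
  stop(sprintf("newick parse error at position %d: %s", pos, msg),
       call. = FALSE)
}

# Returns list(nodes = data.frame(id, label, tag, parent, length, gamma),
#              root = root id).  Whitespace is not allowed inside labels.
.parseNewickNodes <- function(text) {
  if (length(text) != 1 || !is.character(text))
    stop("text must be a single character string")
  chars <- strsplit(text, "")[[1]]
  env <- new.env(parent = emptyenv())
  env$i <- 1L
  env$n <- length(chars)
  env$nodes <- list()

  peek <- function() if (env$i > env$n) "" else chars[env$i]
  advance <- function() env$i <- env$i + 1L
  skipWs <- function() while (env$i <= env$n && grepl("^\\s$", chars[env$i]))
    advance()

  readLabel <- function() {
    out <- character(0)
    while (env$i <= env$n && grepl("^[A-Za-z0-9_.#'+-]$", chars[env$i])) {
      out <- c(out, chars[env$i]); advance()
    }
    paste(out, collapse = "")
  }
  readNumber <- function(what) {
    rest <- paste(chars[env$i:env$n], collapse = "")
    m <- regexpr("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?", rest)
    if (m == -1) .nwkError(env$i, paste("expected", what))
    len <- attr(m, "match.length")
    val <- as.numeric(substr(rest, 1, len))
    env$i <- env$i + len
    val
  }
  addNode <- function(label, tag, parent) {
    id <- length(env$nodes) + 1L
    env$nodes[[id]] <- list(id = id, label = label, tag = tag,
                            parent = parent, length = NA_real_,
                            gamma = NA_real_)
    id
  }
  splitLabel <- function(raw, pos) {
    # "name#H1" / "#H1" / "name" -> c(label, tag)
    if (grepl("#", raw, fixed = TRUE)) {
      parts <- strsplit(raw, "#", fixed = TRUE)[[1]]
      if (length(parts) != 2 || !nzchar(parts[2]))
        .nwkError(pos, "malformed hybrid tag")
      c(parts[1], parts[2])
    } else c(raw, "")
  }

  parseSubtree <- function(parent) {
    skipWs()
    if (peek() == "(") {
      advance()
      id <- addNode("", "", parent)
      repeat {
        parseBranch(id)
        skipWs()
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        .nwkError(env$i, "expected ',' or ')'")
      }
      pos <- env$i
      raw <- readLabel()
      lt <- splitLabel(raw, pos)
      env$nodes[[id]]$label <- lt[1]
      env$nodes[[id]]$tag <- lt[2]
      id
    } else {
      pos <- env$i
      raw <- readLabel()
      if (!nzchar(raw)) .nwkError(pos, "expected a taxon label or '('")
      lt <- splitLabel(raw, pos)
      addNode(lt[1], lt[2], parent)
    }
  }
  parseBranch <- function(parent) {
    id <- parseSubtree(parent)
    skipWs()
    if (peek() == ":") {
      advance()
      env$nodes[[id]]$length <- readNumber("a branch length")
      if (peek() == ":") {          # support field, ignored
        advance()
        if (peek() != ":") readNumber("a support value")
        if (peek() == ":") {
          advance()
          env$nodes[[id]]$gamma <- readNumber("an inheritance weight")
        }
      }
    }
    id
  }

  root <- parseSubtree(NA_integer_)
  skipWs()
  if (peek() != ";") .nwkError(env$i, "expected ';'")
  advance()
  skipWs()
  if (env$i <= env$n) .nwkError(env$i, "trailing characters after ';'")

  nodes <- do.call(rbind, lapply(env$nodes, function(x)
    data.frame(id = x$id, label = x$label, tag = x$tag, parent = x$parent,
               length = x$length, gamma = x$gamma,
               stringsAsFactors = FALSE)))
  list(nodes = nodes, root = root)
}

#' Parse a Newick string into a rooted metric tree
#'
#' Validates the string with the package's position-reporting parser and
#' returns the tree as an \pkg{ape} `phylo` object.  Writing the result
#' with [writeNewick()] and re-parsing yields an identical tree.
#'
#' @param text a single well-formed Newick string with branch lengths
#'   after colons (lengths may be omitted).
#' @return A rooted `phylo` object.
#' @examples
#' parseNewick("((A:1,B:1):1,C:1);")
#' @seealso [parseExtendedNewick()] for networks with a hybrid node.
#' @export
parseNewick <- function(text) {
  parsed <- .parseNewickNodes(text)
  if (any(nzchar(parsed$nodes$tag)))
    stop("hybrid '#H' tag found; use parseExtendedNewick() for networks")
  labs <- parsed$nodes$label
  kids <- parsed$nodes$id %in% parsed$nodes$parent
  if (any(!kids & !nzchar(labs))) stop("unlabeled leaf")
  if (anyDuplicated(labs[!kids])) stop("duplicate taxon labels")
  ape::read.tree(text = text)
}

#' Write trees as Newick, one per line
#'
#' @param trees a `phylo` object or a list of them.
#' @param file path to write to, or `""` to return the lines invisibly.
#' @return The Newick lines, invisibly.
#' @export
writeNewick <- function(trees, file = "") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  lines <- vapply(trees, function(tr) ape::write.tree(tr), character(1))
  if (nzchar(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read gene trees from a file, one Newick per line
#'
#' Each tree is reduced to its unrooted topology; the result is a
#' [GeneTreeSample-class] suitable for [empiricalQuartetTable()] and
#' [inferTree()].
#'
#' @param file path to a file with one Newick string per line.
#' @return A [GeneTreeSample-class].
#' @export
readGeneTrees <- function(file) {
  trees <- ape::read.tree(file)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("no trees in file")
  topos <- lapply(trees, unrootedTopology)
  taxa <- topos[[1]]@taxa
  ok <- vapply(topos, function(t) identical(t@taxa, taxa), logical(1))
  if (!all(ok)) stop("all gene trees must be on the same taxa")
  levels <- vapply(.enumTopo(taxa), topologyId, character(1))
  codes <- match(vapply(topos, topologyId, character(1)), levels)
  new("GeneTreeSample", taxa = taxa, codes = as.integer(codes),
      levels = levels, seed = NA_integer_,
      source = sprintf("read from %s", file), trees = list())
}

#' Parse an extended-Newick string into a single-hybrid network
#'
#' Supports rooted networks with exactly one hybrid node, written with the
#' `#H<id>` tag convention: the hybrid node appears twice, once defining
#' its subtree and once as a bare reference, each occurrence carrying the
#' three-field `length:support:gamma` colon syntax on its (hybrid) parent
#' edge.  The support field is ignored.  Both hybrid edges must carry an
#' inheritance weight, and the two weights must sum to 1 (tolerance 1e-9).
#'
#' @param text a single extended-Newick string.
#' @return A [HybridNetwork-class] object.
#' @examples
#' net <- parseExtendedNewick(
#'   "((((C:1)#H1:1::0.5,B:1)G:1.1,A:1)F:0.1,((#H1:1::0.5,D:1)J:2,E:1)K:0.1)r;")
#' displayedTrees(net)
#' @export
parseExtendedNewick <- function(text) {
  parsed <- .parseNewickNodes(text)
  nodes <- parsed$nodes
  tags <- unique(nodes$tag[nzchar(nodes$tag)])
  if (!length(tags)) stop("no hybrid node ('#H' tag) found")
  if (length(tags) > 1)
    stop("only networks with a single hybrid node are supported")
  occ <- which(nodes$tag == tags)
  if (length(occ) != 2)
    stop(sprintf("hybrid tag '#%s' must occur exactly twice", tags))
  hasKids <- nodes$id %in% nodes$parent
  def <- occ[hasKids[occ]]
  if (length(def) > 1) stop("hybrid node defined with children twice")
  if (length(def) == 0) stop("hybrid node has no descendant subtree")
  ref <- setdiff(occ, def)

  if (anyNA(nodes$gamma[occ]))
    stop("missing inheritance weight (gamma) on a hybrid edge")
  gsum <- sum(nodes$gamma[occ])
  if (abs(gsum - 1) > 1e-9)
    stop(sprintf("hybrid-edge weights must sum to 1 (got %.12g)", gsum))

  # Node names: label if present, else the hybrid tag, else "n<id>".
  nm <- nodes$label
  nm[occ] <- tags
  blank <- !nzchar(nm)
  nm[blank] <- paste0("n", nodes$id[blank])
  if (anyDuplicated(nm[-ref]))
    stop("duplicate node labels in network")

  hybridName <- tags
  edges <- data.frame(parent = character(0), child = character(0),
                      length = numeric(0), gamma = numeric(0),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(nodes))) {
    if (is.na(nodes$parent[i])) next             # root
    child <- if (i == ref) hybridName else nm[i]
    edges <- rbind(edges, data.frame(
      parent = nm[nodes$parent[i]], child = child,
      length = nodes$length[i], gamma = nodes$gamma[i],
      stringsAsFactors = FALSE))
  }
  # Put the defining hybrid edge first so displayedTrees() order follows
  # the order of appearance in the string.
  leaves <- setdiff(nm[!hasKids & seq_len(nrow(nodes)) != ref], hybridName)
  if (anyNA(edges$length)) stop("all network edges must carry a length")
  new("HybridNetwork", taxa = sort(leaves), edges = edges,
      root = nm[parsed$root], hybrid = hybridName, newick = text)
}

# Internal: render a tree stored as an edge table into Newick text.
.edgesToNewick <- function(edges, root) {
  kids <- split(seq_len(nrow(edges)), edges$parent)
  recurse <- function(node) {
    rows <- kids[[node]]
    if (is.null(rows)) return(node)
    inner <- vapply(rows, function(r) {
      paste0(recurse(edges$child[r]), ":",
             sprintf("%.15g", edges$length[r]))
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  paste0(recurse(root), ";")
}
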