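# Glycan compositions and rooted glycan trees.
#
# A glycan tree is a plain nested list: every node is
#   list(code = <monosaccharide code>, children = list(<node>, ...))
# The root is the residue attached to the peptide. Sibling order carries no
# meaning; structural identity is defined by the canonical key, which is
# invariant under any permutation of sibling subtrees.

#' Construct a glycan composition
#'
#' A composition is a named integer vector with one non-negative count per
#' monosaccharide class, in the fixed order of [MONO_CODES].
#'
#' @param ... Named counts, e.g. `glycan_composition(HexNAc = 2, Hex = 3)`.
#' @return Named integer vector of length 5.
#' @export
glycan_composition <- function(...) {
  counts <- c(...)
  comp <- setNames(integer(length(MONO_CODES)), MONO_CODES)
  if (length(counts) > 0L) {
    bad <- setdiff(names(counts), MONO_CODES)
    if (length(bad) > 0L || is.null(names(counts))) {
      stop("unknown monosaccharide code(s): ", paste(bad, collapse = ", "))
    }
    if (any(counts < 0) || any(counts != round(counts))) {
      stop("composition counts must be non-negative integers")
    }
    comp[names(counts)] <- as.integer(counts)
  }
  comp
}

as_composition <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    do.call(glycan_composition, as.list(x[x != 0]))
  } else {
    stop("cannot coerce to glycan composition")
  }
}

#' Mass of a glycan composition
#' @param comp A composition from [glycan_composition()].
#' @return Summed residue mass in Da.
#' @export
composition_mass <- function(comp) {
  comp <- comp[MONO_CODES]
  comp[is.na(comp)] <- 0L
  sum(comp * MONO_MASS)
}

# Display order follows the field's convention (HexNAc before Hex).
.COMP_DISPLAY_ORDER <- c("HexNAc", "Hex", "Fuc", "NeuAc", "NeuGc")

#' Format / parse composition strings like "HexNAc(2)Hex(3)"
#' @param comp A glycan composition.
#' @param text A string such as `"HexNAc(2)Hex(3)Fuc(1)"`.
#' @return `format_composition()` a string; `parse_composition()` a
#'   composition vector.
#' @export
format_composition <- function(comp) {
  comp <- comp[.COMP_DISPLAY_ORDER]
  keep <- comp > 0L
  if (!any(keep)) return("")
  paste0(names(comp)[keep], "(", comp[keep], ")", collapse = "")
}

#' @rdname format_composition
#' @export
parse_composition <- function(text) {
  text <- gsub("\\s", "", text)
  m <- gregexpr("([A-Za-z]+)\\((\\d+)\\)", text)[[1L]]
  if (m[1L] == -1L || sum(attr(m, "match.length")) != nchar(text)) {
    stop("malformed composition string: ", text)
  }
  parts <- regmatches(text, gregexpr("[A-Za-z]+\\(\\d+\\)", text))[[1L]]
  codes <- sub("\\(.*", "", parts)
  counts <- as.integer(sub(".*\\((\\d+)\\)", "\\1", parts))
  bad <- setdiff(codes, MONO_CODES)
  if (length(bad) > 0L) stop("unknown monosaccharide code(s): ",
                             paste(bad, collapse = ", "))
  comp <- setNames(integer(length(MONO_CODES)), MONO_CODES)
  for (i in seq_along(codes)) comp[codes[i]] <- comp[codes[i]] + counts[i]
  comp
}

#' Construct a glycan tree node
#'
#' @param code Monosaccharide code of the node.
#' @param children List of child nodes (order irrelevant).
#' @return A node (nested list); the root node represents the whole tree.
#' @export
glycan_node <- function(code, children = list()) {
  if (!code %in% MONO_CODES) stop("unknown monosaccharide code: ", code)
  list(code = code, children = children)
}

#' Composition of a glycan tree
#' @param tree Root node.
#' @return Named integer composition vector.
#' @export
tree_composition <- function(tree) {
  comp <- setNames(integer(length(MONO_CODES)), MONO_CODES)
  walk <- function(node) {
    comp[node$code] <<- comp[node$code] + 1L
    for (ch in node$children) walk(ch)
  }
  walk(tree)
  comp
}

#' @rdname tree_composition
#' @export
tree_mass <- function(tree) composition_mass(tree_composition(tree))

#' @rdname tree_composition
#' @export
tree_size <- function(tree) sum(tree_composition(tree))

#' Canonical key of a glycan tree
#'
#' Two trees are structurally equal iff their canonical keys are equal;
#' the key is invariant under any permutation of sibling subtrees.
#'
#' @param tree Root node.
#' @return A string key.
#' @export
canonical_key <- function(tree) {
  if (length(tree$children) == 0L) return(tree$code)
  keys <- sort(vapply(tree$children, canonical_key, character(1)),
               method = "radix")
  paste0(tree$code, "(", paste(keys, collapse = ","), ")")
}

#' Structural equality of two glycan trees
#' @param a,b Root nodes.
#' @return `TRUE` iff the trees are identical up to sibling order.
#' @export
structure_equal <- function(a, b) {
  identical(canonical_key(a), canonical_key(b))
}

#' Write a glycan tree in the native indented dialect
#'
#' One residue per line; depth is encoded as two spaces of indentation per
#' level. Children are emitted in canonical (sorted-key) order so that
#' `write_glycan()` is a canonical form.
#'
#' @param tree Root node.
#' @return A single string (lines joined with `\n`).
#' @export
write_glycan <- function(tree) {
  lines <- character(0)
  emit <- function(node, depth) {
    lines[[length(lines) + 1L]] <<- paste0(strrep("  ", depth), node$code)
    ord <- order(vapply(node$children, canonical_key, character(1)),
                 method = "radix")
    for (ch in node$children[ord]) emit(ch, depth + 1L)
  }
  emit(tree, 0L)
  paste(lines, collapse = "\n")
}

#' Parse a glycan tree from the native indented dialect
#'
#' @param text Either a single string with embedded newlines or a character
#'   vector of lines. Indentation must be two spaces per depth level; each
#'   line is one monosaccharide code.
#' @return Root node of the parsed tree.
#' @export
parse_glycan <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]]
           else text
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0L) stop("empty glycan text")
  indents <- nchar(lines) - nchar(sub("^ *", "", lines))
  if (any(indents %% 2L != 0L)) {
    stop("bad indentation (must be multiples of two spaces) at line: ",
         lines[which(indents %% 2L != 0L)[1L]])
  }
  depth <- indents %/% 2L
  codes <- trimws(lines)
  bad <- setdiff(codes, MONO_CODES)
  if (length(bad) > 0L) stop("unknown residue token: ", bad[1L])
  if (depth[1L] != 0L) stop("first line must be the (unindented) root")
  if (sum(depth == 0L) > 1L) {
    stop("orphan node: multiple roots found at token ",
         codes[which(depth == 0L)[2L]])
  }
  # Recursive descent over the line block.
  build <- function(i) {
    node <- glycan_node(codes[i])
    j <- i + 1L
    while (j <= length(codes) && depth[j] > depth[i]) {
      if (depth[j] != depth[i] + 1L) {
        stop("orphan node (indentation jump) at token: ", codes[j])
      }
      res <- build(j)
      node$children[[length(node$children) + 1L]] <- res$node
      j <- res$nxt
    }
    list(node = node, nxt = j)
  }
  build(1L)$node
}

#' Construct a glycan database record
#'
#' @param tree Root node (may be `NULL` for composition-only records, in
#'   which case a linear chain in canonical composition order is assembled
#'   as a synthetic stand-in structure).
#' @param id Record identifier.
#' @param link_type `"N"` or `"O"`.
#' @param composition Optional composition (required when `tree` is NULL).
#' @return A `glycan_record` list with fields `id`, `tree`, `composition`,
#'   `mass`, `key`, `link_type`, `structure_inferred`.
#' @export
glycan_record <- function(tree = NULL, id = NA_character_, link_type = "N",
                          composition = NULL) {
  inferred <- FALSE
  if (is.null(tree)) {
    if (is.null(composition)) stop("need a tree or a composition")
    tree <- chain_from_composition(composition)
    inferred <- TRUE
  }
  comp <- tree_composition(tree)
  if (!is.null(composition) && !identical(unname(comp),
                                          unname(composition[MONO_CODES]))) {
    stop("tree composition disagrees with the stated composition")
  }
  structure(list(
    id = id,
    tree = tree,
    composition = comp,
    mass = composition_mass(comp),
    key = canonical_key(tree),
    link_type = match.arg(link_type, c("N", "O")),
    structure_inferred = inferred,
    # cached theoretical fragment sets (glycan-only neutral masses)
    y_masses = sort(unique(round(enumerate_y_fragments(tree, 0)$glycan_mass,
                                 6))),
    b_masses = sort(unique(round(enumerate_b_fragments(tree)$neutral_mass,
                                 6)))
  ), class = "glycan_record")
}

# Linear chain in display order (HexNAc first): used only as a synthetic
# stand-in structure for composition-only database entries.
chain_from_composition <- function(comp) {
  codes <- rep(.COMP_DISPLAY_ORDER, comp[.COMP_DISPLAY_ORDER])
  if (length(codes) == 0L) stop("empty composition")
  node <- glycan_node(codes[length(codes)])
  for (code in rev(codes[-length(codes)])) {
    node <- glycan_node(code, list(node))
  }
  node
}

#' Read / write a glycan structure database
#'
#' The native database format is FASTA-like: a header line `"> id [N|O]"`
#' followed by one tree in the indented dialect. Header lines whose body is
#' a single `"Code(n)..."` composition string are accepted as
#' composition-only records.
#'
#' @param path File path.
#' @param records List of `glycan_record` objects (for the writer).
#' @return `read_glycan_db()` a list of [glycan_record()]s.
#' @export
read_glycan_db <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no '>' record headers in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  records <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    header <- trimws(sub("^>", "", lines[starts[k]]))
    toks <- strsplit(header, "\\s+")[[1L]]
    id <- toks[1L]
    link <- if (length(toks) > 1L && toks[2L] %in% c("N", "O")) toks[2L] else "N"
    body <- lines[(starts[k] + 1L):ends[k]]
    body <- body[trimws(body) != ""]
    if (length(body) == 0L) stop("record ", id, " has no body")
    if (length(body) == 1L && grepl("\\(", body) && !grepl("^ ", body)) {
      comp <- parse_composition(body)
      records[[k]] <- glycan_record(NULL, id = id, link_type = link,
                                    composition = comp)
    } else {
      records[[k]] <- glycan_record(parse_glycan(body), id = id,
                                    link_type = link)
    }
  }
  records
}

#' @rdname read_glycan_db
#' @export
write_glycan_db <- function(records, path) {
  out <- character(0)
  for (rec in records) {
    out <- c(out, paste0("> ", rec$id, " ", rec$link_type),
             strsplit(write_glycan(rec$tree), "\n", fixed = TRUE)[[1L]], "")
  }
  writeLines(out, path)
  invisible(path)
}
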