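# Restricted GlycoCT reader.
#
# Many public glycan structure databases ship in GlycoCT condensed format.
# Only the information the search engine consumes is read: the RES / LIN
# sections, the five monosaccharide classes, and parent-child connectivity.
# Linkage positions, anomeric configuration and ring size are ignored.
#
# Residue classification:
#   * HEX superclass                      -> Hex
#   * HEX with an n-acetyl substituent    -> HexNAc
#   * HEX with a deoxy modifier (|6:d)    -> Fuc
#   * NON with n-acetyl                   -> NeuAc
#   * NON with n-glycolyl                 -> NeuGc

#' Parse a glycan tree from a restricted GlycoCT (condensed) record
#'
#' @param text A single string or character vector of lines containing the
#'   `RES` and `LIN` sections of one GlycoCT condensed record.
#' @return Root node of the glycan tree (see [glycan_node()]).
#' @export
parse_glycoct <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]]
           else text
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  res_at <- match("RES", lines)
  if (is.na(res_at)) stop("GlycoCT record has no RES section")
  lin_at <- match("LIN", lines)
  res_lines <- if (is.na(lin_at)) lines[-seq_len(res_at)]
               else lines[(res_at + 1L):(lin_at - 1L)]
  lin_lines <- if (is.na(lin_at)) character(0)
               else lines[(lin_at + 1L):length(lines)]

  m <- regmatches(res_lines, regexec("^(\\d+)([bs]):(.*)$", res_lines))
  if (any(vapply(m, length, integer(1)) != 4L)) {
    stop("malformed RES line: ",
         res_lines[which(vapply(m, length, integer(1)) != 4L)[1L]])
  }
  ids <- vapply(m, function(x) as.integer(x[2L]), integer(1))
  kinds <- vapply(m, function(x) x[3L], character(1))
  bodies <- vapply(m, function(x) x[4L], character(1))

  # parent/child pairs; positions and anomers inside (...) are ignored
  parent <- integer(0); child <- integer(0)
  if (length(lin_lines) > 0L) {
    lm <- regmatches(lin_lines,
                     regexec("^\\d+:(\\d+)[a-z]\\([^)]*\\)(\\d+)[a-z]$",
                             lin_lines))
    if (any(vapply(lm, length, integer(1)) != 3L)) {
      stop("malformed LIN line: ",
           lin_lines[which(vapply(lm, length, integer(1)) != 3L)[1L]])
    }
    parent <- vapply(lm, function(x) as.integer(x[2L]), integer(1))
    child <- vapply(lm, function(x) as.integer(x[3L]), integer(1))
  }

  is_base <- kinds == "b"
  subst_of <- setNames(rep(NA_integer_, length(ids)), ids)
  # map substituent id -> parent base id
  for (i in seq_along(parent)) {
    if (!is_base[match(child[i], ids)]) {
      subst_of[as.character(child[i])] <- parent[i]
    }
  }

  classify <- function(i) {
    body <- bodies[i]
    substs <- bodies[!is_base & !is.na(subst_of) &
                       subst_of == ids[i]]
    has_acetyl <- any(grepl("n-acetyl", substs, fixed = TRUE))
    has_glycolyl <- any(grepl("n-glycolyl", substs, fixed = TRUE))
    if (grepl("-HEX-", body) || grepl("HEX-", body)) {
      deoxy <- grepl("\\|6:d", body) || grepl("\\|\\d:d.*HEX", body)
      if (deoxy) return("Fuc")
      if (has_acetyl) return("HexNAc")
      return("Hex")
    }
    if (grepl("-NON-", body)) {
      if (has_glycolyl) return("NeuGc")
      if (has_acetyl) return("NeuAc")
      stop("unsupported NON residue (no n-acetyl/n-glycolyl): ", body)
    }
    stop("unsupported GlycoCT residue: ", body)
  }

  base_ids <- ids[is_base]
  codes <- setNames(vapply(which(is_base), classify, character(1)), base_ids)

  kids <- split(child[child %in% base_ids & parent %in% base_ids],
                parent[child %in% base_ids & parent %in% base_ids])
  roots <- setdiff(base_ids, child)
  if (length(roots) != 1L) {
    stop("GlycoCT record must have exactly one root residue, found ",
         length(roots))
  }
  seen <- integer(0)
  build <- function(id) {
    if (id %in% seen) stop("cycle detected at residue ", id)
    seen <<- c(seen, id)
    ch <- kids[[as.character(id)]]
    glycan_node(codes[[as.character(id)]],
                lapply(if (is.null(ch)) integer(0) else sort(ch), build))
  }
  tree <- build(roots)
  if (length(seen) != length(base_ids)) {
    stop("orphan residue(s) not connected to the root: ",
         paste(setdiff(base_ids, seen), collapse = ", "))
  }
  tree
}

#' Read a multi-record GlycoCT database file
#'
#' Records are separated by blank lines; an optional comment/header line
#' starting with `#` or `>` before each record provides the id.
#'
#' @param path File path.
#' @param link_type Link type assigned to all records (`"N"` or `"O"`).
#' @return List of [glycan_record()]s.
#' @export
read_glycoct_db <- function(path, link_type = "N") {
  lines <- readLines(path, warn = FALSE)
  grp <- cumsum(trimws(lines) == "")
  blocks <- split(lines, grp)
  blocks <- Filter(function(b) any(trimws(b) != ""), blocks)
  out <- list()
  for (b in blocks) {
    b <- b[trimws(b) != ""]
    id <- NA_character_
    hdr <- grepl("^[#>]", b)
    if (any(hdr)) {
      id <- trimws(sub("^[#>]+", "", b[hdr][1L]))
      b <- b[!hdr]
    }
    if (is.na(id)) id <- paste0("glycoct_", length(out) + 1L)
    out[[length(out) + 1L]] <- glycan_record(parse_glycoct(b), id = id,
                                             link_type = link_type)
  }
  out
}
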