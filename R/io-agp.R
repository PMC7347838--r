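agp_cols <- c("object", "object_beg", "object_end", "part_number",
              "component_type", "component_id", "component_beg",
              "component_end", "orientation", "gap_length", "gap_type",
              "linkage", "linkage_evidence")

#' Build a chromosome assembly (AGP) from ordered placements
#'
#' A chromosome assembly is an ordered tiling of components (contigs or
#' scaffolds, rows with `type = "W"`) and gaps (`type = "N"`) along each
#' object (chromosome). Object coordinates are computed from the row order
#' and component/gap lengths, so placements can never overlap; rows for one
#' object must be contiguous and in placement order.
#'
#' @param placements data.frame with columns `object`, `type` ("W" or "N"),
#'   `id` (component id, `NA` for gaps), `length` (component or gap length,
#'   bp), `orientation` ("+"/"-", `NA` for gaps). Optional columns
#'   `gap_type`, `linkage`, `linkage_evidence` override the gap defaults
#'   `"scaffold"`, `"yes"`, `"paired-ends"`.
#' @return data.frame of class `agp` with 1-based inclusive object and
#'   component coordinates.
#' @export
agp_assembly <- function(placements) {
  need <- c("object", "type", "id", "length", "orientation")
  fail_if(!all(need %in% names(placements)), "placements need columns: %s",
          paste(setdiff(need, names(placements)), collapse = ", "))
  p <- placements
  fail_if(any(!p$type %in% c("W", "N")), "placement type must be 'W' or 'N'")
  fail_if(any(p$length <= 0), "placement lengths must be > 0")
  fail_if(any(p$type == "W" & (is.na(p$id) | !nzchar(p$id))),
          "component rows need an id")
  fail_if(any(p$type == "W" & !p$orientation %in% c("+", "-")),
          "component rows need orientation '+' or '-'")
  # objects must occupy contiguous row blocks
  blocks <- rle(as.character(p$object))$values
  fail_if(anyDuplicated(blocks) > 0,
          "rows for one object must be contiguous (object %s repeats)",
          blocks[duplicated(blocks)][1])
  out <- do.call(rbind, lapply(split(seq_len(nrow(p)), factor(p$object, levels = blocks)),
                               function(ix) {
    q <- p[ix, , drop = FALSE]
    ends <- cumsum(q$length)
    begs <- ends - q$length + 1
    data.frame(
      object = q$object,
      object_beg = begs,
      object_end = ends,
      part_number = seq_along(ix),
      component_type = q$type,
      component_id = ifelse(q$type == "W", q$id, NA_character_),
      component_beg = ifelse(q$type == "W", 1, NA_real_),
      component_end = ifelse(q$type == "W", q$length, NA_real_),
      orientation = ifelse(q$type == "W", q$orientation, NA_character_),
      gap_length = ifelse(q$type == "N", q$length, NA_real_),
      gap_type = ifelse(q$type == "N",
                        if ("gap_type" %in% names(q)) q$gap_type else "scaffold",
                        NA_character_),
      linkage = ifelse(q$type == "N",
                       if ("linkage" %in% names(q)) q$linkage else "yes",
                       NA_character_),
      linkage_evidence = ifelse(q$type == "N",
                                if ("linkage_evidence" %in% names(q)) q$linkage_evidence
                                else "paired-ends",
                                NA_character_),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("agp", "data.frame")
  out
}

validate_agp <- function(agp) {
  fail_if(!all(agp_cols %in% names(agp)), "not an AGP assembly table")
  for (obj in unique(agp$object)) {
    a <- agp[agp$object == obj, , drop = FALSE]
    a <- a[order(a$part_number), , drop = FALSE]
    fail_if(a$object_beg[1] != 1, "object %s does not start at 1", obj)
    if (nrow(a) > 1) {
      fail_if(any(a$object_beg[-1] != a$object_end[-nrow(a)] + 1),
              "overlapping or non-contiguous placements on object %s", obj)
    }
    fail_if(any(a$object_end < a$object_beg), "negative span on object %s", obj)
  }
  invisible(agp)
}

#' Write a chromosome assembly to an AGP v2.1 file
#'
#' Component rows are type `W`, gap rows type `N` with an explicit length.
#' Coordinates are 1-based inclusive. `read_agp(write_agp(x))` reproduces
#' `x` exactly.
#'
#' @param agp An `agp` assembly (see [agp_assembly()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  validate_agp(agp)
  num <- function(x) ifelse(is.na(x), "na", format(x, scientific = FALSE, trim = TRUE))
  isW <- agp$component_type == "W"
  c6 <- ifelse(isW, agp$component_id, num(agp$gap_length))
  c7 <- ifelse(isW, num(agp$component_beg), agp$gap_type)
  c8 <- ifelse(isW, num(agp$component_end), agp$linkage)
  c9 <- ifelse(isW, agp$orientation, agp$linkage_evidence)
  lines <- paste(agp$object, num(agp$object_beg), num(agp$object_end),
                 num(agp$part_number), agp$component_type, c6, c7, c8, c9,
                 sep = "\t")
  writeLines(c("##agp-version\t2.1", lines), path)
  invisible(path)
}

#' Read an AGP v2.1 file
#'
#' @param path Path to an AGP file (comment lines starting with `#` are
#'   skipped).
#' @return data.frame of class `agp`.
#' @export
read_agp <- function(path) {
  fail_if(!file.exists(path), "AGP file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  fail_if(any(nf < 9), "AGP line %d has %d columns (9 required)",
          which(nf < 9)[1], nf[which(nf < 9)[1]])
  m <- t(vapply(fields, function(f) f[1:9], character(9)))
  isW <- m[, 5] == "W"
  out <- data.frame(
    object = m[, 1],
    object_beg = as.numeric(m[, 2]),
    object_end = as.numeric(m[, 3]),
    part_number = as.numeric(m[, 4]),
    component_type = m[, 5],
    component_id = ifelse(isW, m[, 6], NA_character_),
    component_beg = ifelse(isW, suppressWarnings(as.numeric(m[, 7])), NA_real_),
    component_end = ifelse(isW, suppressWarnings(as.numeric(m[, 8])), NA_real_),
    orientation = ifelse(isW, m[, 9], NA_character_),
    gap_length = ifelse(!isW, suppressWarnings(as.numeric(m[, 6])), NA_real_),
    gap_type = ifelse(!isW, m[, 7], NA_character_),
    linkage = ifelse(!isW, m[, 8], NA_character_),
    linkage_evidence = ifelse(!isW, m[, 9], NA_character_),
    stringsAsFactors = FALSE)
  class(out) <- c("agp", "data.frame")
  validate_agp(out)
}

#' Object (chromosome) lengths of an AGP assembly
#'
#' @param agp An `agp` assembly.
#' @return Named numeric vector of object lengths.
#' @export
agp_object_lengths <- function(agp) {
  validate_agp(agp)
  vapply(split(agp$object_end, agp$object), max, numeric(1))
}
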