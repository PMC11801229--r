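#' Region ontology
#'
#' A flattened structure ontology: one row per region with a unique id, an
#' acronym, a display name and a parent id (NA for the root). Compatible with
#' flattened reference-atlas structure-ontology exports but not dependent on
#' them.
#'
#' @param df data.frame with columns `id`, `acronym`, `name`, `parent_id`.
#' @return an object of class `ontology`.
#' @export
ontology <- function(df) {
  need <- c("id", "acronym", "name", "parent_id")
  if (!all(need %in% names(df)))
    stop("ontology needs columns id, acronym, name, parent_id")
  if (anyDuplicated(df$id)) stop("ontology ids must be unique")
  if (!any(is.na(df$parent_id))) stop("ontology must contain a root (parent_id NA)")
  out <- df[, need]
  class(out) <- c("ontology", "data.frame")
  check_acyclic(out)
  out
}

#' Read an ontology CSV (columns id, acronym, name, parent_id)
#' @param path CSV file path.
#' @return an [ontology()].
#' @examples
#' ont <- read_ontology(system.file("extdata", "example_ontology.csv",
#'                                  package = "historeg"))
#' ont$acronym
#' @export
read_ontology <- function(path) {
  ontology(read.csv(path, stringsAsFactors = FALSE))
}

check_acyclic <- function(ont) {
  parent <- ont$parent_id[match(ont$id, ont$id)]
  for (start in ont$id) {
    seen <- integer(0)
    cur <- start
    while (!is.na(cur)) {
      if (cur %in% seen) stop("ontology parent links contain a cycle")
      seen <- c(seen, cur)
      cur <- ont$parent_id[match(cur, ont$id)]
      if (length(cur) == 0L) break
    }
  }
  invisible(TRUE)
}

# ancestors of id from itself up to the root (inclusive)
ancestry <- function(ont, id) {
  out <- integer(0)
  cur <- id
  while (length(cur) == 1L && !is.na(cur)) {
    out <- c(out, cur)
    cur <- ont$parent_id[match(cur, ont$id)]
  }
  out
}

region_table_row <- function(region_id, acronym, total_px, signal_px, cell_count) {
  data.frame(region_id = region_id, acronym = acronym, total_px = total_px,
             signal_px = signal_px,
             proportion = ifelse(total_px > 0, signal_px / total_px, 0),
             cell_count = cell_count)
}

#' Count signal pixels per region
#'
#' Tallies, for every region id present in the warped label image (plus
#' background 0, reported as "unassigned"), the total pixel count, the
#' signal-mask-positive pixel count and their proportion.
#'
#' @param mask logical signal mask.
#' @param labels integer label image, same shape.
#' @param ont optional [ontology()] supplying acronyms.
#' @return a `region_table` data.frame with columns `region_id, acronym,
#'   total_px, signal_px, proportion, cell_count` (cell_count 0 here).
#' @export
count_pixels_by_region <- function(mask, labels, ont = NULL) {
  if (!identical(dim(mask), dim(labels)))
    stop("'mask' and 'labels' must have the same shape")
  ids <- sort(unique(as.vector(labels)))
  lab_f <- factor(as.vector(labels), levels = ids)
  total <- as.integer(table(lab_f))
  signal <- as.integer(tapply(as.vector(mask) + 0L, lab_f, sum, default = 0L))
  acr <- region_acronyms(ids, ont)
  out <- region_table_row(ids, acr, total, signal, 0L)
  class(out) <- c("region_table", "data.frame")
  out
}

region_acronyms <- function(ids, ont) {
  acr <- ifelse(ids == 0, "unassigned", paste0("region_", ids))
  if (!is.null(ont)) {
    m <- match(ids, ont$id)
    acr[!is.na(m)] <- ont$acronym[m[!is.na(m)]]
  }
  acr
}

#' Assign detections to regions by box center
#'
#' Each detection is counted under the label id at its box center pixel;
#' centers on background (label 0) or outside the label image count under
#' "unassigned" (id 0). Box-center assignment is cheap and deterministic;
#' swap in a custom rule by editing the detections before counting.
#'
#' @param detections detections data.frame (1-based pixel-center
#'   coordinates).
#' @param labels integer label image.
#' @param ont optional [ontology()] supplying acronyms.
#' @return a `region_table` data.frame (signal_px 0 here).
#' @export
assign_detections_to_regions <- function(detections, labels, ont = NULL) {
  H <- nrow(labels); W <- ncol(labels)
  ids <- sort(unique(c(0L, as.vector(labels))))
  counts <- setNames(integer(length(ids)), ids)
  if (nrow(detections) > 0L) {
    cx <- clamp(round((detections$x_min + detections$x_max) / 2), 1, W)
    cy <- clamp(round((detections$y_min + detections$y_max) / 2), 1, H)
    hit <- labels[cbind(cy, cx)]
    t <- table(factor(hit, levels = ids))
    counts <- as.integer(t)
  }
  acr <- region_acronyms(ids, ont)
  out <- region_table_row(ids, acr, 0L, 0L, as.integer(counts))
  class(out) <- c("region_table", "data.frame")
  out
}

#' Merge pixel and detection region tables
#'
#' @param pixels table from [count_pixels_by_region()].
#' @param cells table from [assign_detections_to_regions()].
#' @return combined `region_table`.
#' @export
merge_region_tables <- function(pixels, cells) {
  ids <- sort(union(pixels$region_id, cells$region_id))
  mp <- match(ids, pixels$region_id); mc <- match(ids, cells$region_id)
  total <- ifelse(is.na(mp), 0L, pixels$total_px[mp])
  signal <- ifelse(is.na(mp), 0L, pixels$signal_px[mp])
  cellc <- ifelse(is.na(mc), 0L, cells$cell_count[mc])
  acr <- ifelse(is.na(mp), cells$acronym[mc], pixels$acronym[mp])
  out <- region_table_row(ids, acr, total, signal, cellc)
  class(out) <- c("region_table", "data.frame")
  out
}

#' Roll a region table up to a set of ancestor regions
#'
#' Sums each row into its nearest ancestor (walking parent links) whose
#' acronym is in `level`; rows with no target ancestor are kept under their
#' own id, so totals are preserved exactly. Integer arithmetic throughout.
#'
#' @param table a `region_table`.
#' @param ont an [ontology()].
#' @param level character vector of target acronyms.
#' @return the rolled-up `region_table`.
#' @export
rollup <- function(table, ont, level) {
  stopifnot(inherits(ont, "ontology"))
  missing_acr <- setdiff(level, ont$acronym)
  if (length(missing_acr))
    stop("acronyms not in ontology: ", paste(missing_acr, collapse = ", "))
  check_acyclic(ont)
  targets <- ont$id[ont$acronym %in% level]
  dest <- vapply(table$region_id, function(id) {
    anc <- ancestry(ont, id)
    hit <- anc[anc %in% targets]
    if (length(hit)) hit[1] else id          # nearest target ancestor
  }, numeric(1))
  ids <- sort(unique(dest))
  agg <- function(v) as.integer(tapply(v, factor(dest, levels = ids), sum,
                                       default = 0L))
  out <- region_table_row(ids, region_acronyms(ids, ont),
                          agg(table$total_px), agg(table$signal_px),
                          agg(table$cell_count))
  class(out) <- c("region_table", "data.frame")
  out
}

#' Write a region table CSV
#' @param table a `region_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
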