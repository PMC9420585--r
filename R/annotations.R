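#' Pixel-to-sample mapping
#'
#' Annotations are drawn on a rendered waveform image; a horizontal pixel
#' position `P` maps to the sample index `S = round(P / W * L)`, where `W`
#' is the image width and `L` the signal length. With the default 2264-pixel
#' image and 2160-sample records the mapping loses less than one sample to
#' rounding. Rounding is half-away-from-zero; endpoints are interval bounds
#' in the 0-based half-open convention.
#'
#' @param W image width in pixels (default 2264).
#' @param H image height in pixels (informational; default 1296).
#' @param L signal length in samples (default 2160).
#' @return object of class `pixel_mapping`.
#' @export
pixel_mapping <- function(W = 2264, H = 1296, L = 2160) {
  if (W <= 0 || L <= 0) stop("W and L must be positive")
  structure(list(W = W, H = H, L = L), class = "pixel_mapping")
}

# round half away from zero (base round() is banker's rounding)
.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Map a pixel position to a sample index
#'
#' @param P pixel position(s) in `[0, W]`.
#' @param m a [pixel_mapping()].
#' @return sample bound(s) in `[0, L]` (0-based interval endpoints).
#' @export
px_to_sample <- function(P, m = pixel_mapping()) {
  if (any(P < 0 | P > m$W)) stop("pixel position outside [0, W]")
  pmin(m$L, pmax(0, .round_half_up(P / m$W * m$L)))
}

#' Map a sample index to a pixel position
#'
#' Inverse mapping used by the annotation fixture writer.
#'
#' @param S sample bound(s) in `[0, L]`.
#' @param m a [pixel_mapping()].
#' @return pixel position(s) in `[0, W]`.
#' @export
sample_to_px <- function(S, m = pixel_mapping()) {
  if (any(S < 0 | S > m$L)) stop("sample index outside [0, L]")
  pmin(m$W, pmax(0, .round_half_up(S / m$L * m$W)))
}

#' Construct an annotation set
#'
#' @param spans data.frame with columns `label` ("systole"/"diastole"),
#'   `start_px`, `end_px`.
#' @param mapping a [pixel_mapping()].
#' @param record_id identifier of the annotated record.
#' @return object of class `annotation_set`, spans sorted by `start_px`.
#' @export
annotation_set <- function(spans, mapping = pixel_mapping(), record_id = "rec") {
  stopifnot(is.data.frame(spans),
            all(c("label", "start_px", "end_px") %in% names(spans)))
  if (nrow(spans) > 0) {
    lab <- tolower(spans$label)
    bad <- setdiff(unique(lab), c("systole", "diastole"))
    if (length(bad)) stop("unknown annotation label(s): ", paste(bad, collapse = ", "))
    spans$label <- lab
    if (any(spans$start_px >= spans$end_px)) stop("spans must satisfy start_px < end_px")
    if (any(spans$start_px < 0 | spans$end_px > mapping$W)) {
      stop("spans must lie within [0, W]")
    }
    spans <- spans[order(spans$start_px), , drop = FALSE]
    rownames(spans) <- NULL
    for (cls in c("systole", "diastole")) {
      s <- spans[spans$label == cls, , drop = FALSE]
      if (nrow(s) > 1 && any(s$start_px[-1] < s$end_px[-nrow(s)])) {
        stop("overlapping ", cls, " spans")
      }
    }
  }
  structure(list(spans = spans, mapping = mapping,
                 record_id = as.character(record_id)),
            class = "annotation_set")
}

#' Parse a LabelMe-dialect annotation file
#'
#' Reads the JSON dialect produced by the LabelMe tool: top-level
#' `imagePath`, `imageWidth`, `imageHeight` and a `shapes` array whose
#' entries carry a `label`, a list of `[x, y]` points and a `shape_type`.
#' Only the horizontal extent of each shape is meaningful: rectangles use
#' their two x-coordinates, polygons their x-range. Labels are matched
#' case-insensitively against "systole"/"diastole".
#'
#' @param path JSON file path.
#' @param mapping fallback [pixel_mapping()] if the file lacks image
#'   dimensions; `L` is always taken from `mapping`.
#' @return an [annotation_set()].
#' @export
load_labelme <- function(path, mapping = pixel_mapping()) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  W <- if (!is.null(j$imageWidth)) j$imageWidth else mapping$W
  H <- if (!is.null(j$imageHeight)) j$imageHeight else mapping$H
  m <- pixel_mapping(W = W, H = H, L = mapping$L)
  shapes <- j$shapes
  if (is.null(shapes)) shapes <- list()
  spans <- do.call(rbind, lapply(shapes, function(s) {
    xs <- vapply(s$points, function(p) as.numeric(p[[1]]), numeric(1))
    data.frame(label = as.character(s$label),
               start_px = min(xs), end_px = max(xs),
               stringsAsFactors = FALSE)
  }))
  if (is.null(spans)) {
    spans <- data.frame(label = character(0), start_px = numeric(0),
                        end_px = numeric(0), stringsAsFactors = FALSE)
  }
  rid <- if (!is.null(j$imagePath)) sub("\\.[^.]*$", "", basename(j$imagePath)) else "rec"
  annotation_set(spans, mapping = m, record_id = rid)
}

#' Write a LabelMe-dialect annotation file
#'
#' Fixture writer: converts a label sequence into systole/diastole rectangle
#' shapes with synthetic pixel coordinates, round-trippable through
#' [load_labelme()] and [annotation_to_labels()].
#'
#' @param labels integer label vector (values 0/1/2).
#' @param path output JSON path.
#' @param mapping a [pixel_mapping()]; `L` must equal `length(labels)`.
#' @param record_id identifier written as `imagePath`.
#' @export
write_labelme <- function(labels, path, mapping = pixel_mapping(L = length(labels)),
                          record_id = "rec") {
  if (mapping$L != length(labels)) stop("mapping$L must equal length(labels)")
  iv <- labels_to_intervals(labels, record_id)
  shapes <- lapply(seq_len(nrow(iv)), function(i) {
    x1 <- sample_to_px(iv$start[i], mapping)
    x2 <- sample_to_px(iv$end[i], mapping)
    list(
      label = if (iv$phase[i] == 1L) "systole" else "diastole",
      points = list(c(x1, 0.1 * mapping$H), c(x2, 0.9 * mapping$H)),
      shape_type = "rectangle"
    )
  })
  jsonlite::write_json(
    list(imagePath = paste0(record_id, ".png"),
         imageWidth = mapping$W, imageHeight = mapping$H,
         shapes = shapes),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Build a per-sample label sequence from an annotation set
#'
#' Each span's pixel extent is mapped through [px_to_sample()]; the mapped
#' bounds are 0-based half-open, so a boundary sample shared by adjacent
#' systole/diastole spans belongs to the later phase.
#'
#' @param ann an [annotation_set()].
#' @return integer label vector of length `mapping$L`.
#' @export
annotation_to_labels <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  m <- ann$mapping
  classes <- integer(m$L)
  sp <- ann$spans
  for (i in seq_len(nrow(sp))) {
    s <- px_to_sample(sp$start_px[i], m)
    e <- px_to_sample(sp$end_px[i], m)
    if (s >= e) stop(sprintf("span %d collapses after rounding (%d >= %d)", i, s, e))
    classes[(s + 1L):e] <- if (sp$label[i] == "systole") 1L else 2L
  }
  classes
}

#' Split records into train / validation / test sets
#'
#' Deterministic seeded split, by default stratified by pulse type so each
#' subset preserves the per-type composition (per-type accuracy reports then
#' have support in the test set). Within each stratum the validation and
#' test shares are `floor(n * r)` with the remainder going to training.
#'
#' @param records list whose elements carry a `pulse_record` under `$record`
#'   (the [generate_dataset()] shape) or are `pulse_record`s themselves.
#' @param ratio positive weights for train/validation/test (default `8:1:1`).
#' @param seed integer seed.
#' @param stratify_by_type stratify on the records' `pulse_type` (default
#'   TRUE).
#' @return list with `train`, `val`, `test` (disjoint index vectors into
#'   `records`, exhaustive).
#' @export
split_dataset <- function(records, ratio = c(8, 1, 1), seed = 1L,
                          stratify_by_type = TRUE) {
  if (length(ratio) != 3L || any(ratio <= 0)) stop("ratio must be three positive weights")
  n <- length(records)
  if (n < 3L) stop("need at least 3 records to form a 3-way split")
  get_type <- function(r) if (inherits(r, "pulse_record")) r$pulse_type else r$record$pulse_type
  types <- vapply(records, get_type, character(1))
  r <- ratio / sum(ratio)
  set.seed(as.integer(seed))
  train <- integer(0); val <- integer(0); test <- integer(0)
  strata <- if (stratify_by_type) split(seq_len(n), types) else list(all = seq_len(n))
  for (idx in strata) {
    idx <- idx[sample.int(length(idx))]
    m <- length(idx)
    n_val <- floor(m * r[2]); n_test <- floor(m * r[3])
    test <- c(test, idx[seq_len(n_test)])
    val <- c(val, idx[n_test + seq_len(n_val)])
    train <- c(train, idx[setdiff(seq_len(m), seq_len(n_test + n_val))])
  }
  list(train = sort(train), val = sort(val), test = sort(test))
}
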