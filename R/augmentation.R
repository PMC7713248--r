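#' Horizontal flip
#'
#' Reverses column order. An involution: flipping twice restores the input.
#' Nodules look alike in the left and right lobes, which is what makes the
#' mirrored crop a legitimate training example.
#'
#' @param img matrix or `h x w x c` array of intensities.
#' @return same shape, columns reversed.
#' @export
horizontal_flip <- function(img) {
  if (is.matrix(img)) return(img[, rev(seq_len(ncol(img))), drop = FALSE])
  stopifnot(length(dim(img)) == 3)
  img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
}

#' Percentile histogram stretching
#'
#' Linear contrast expansion: the `p_low` and `p_high` intensity percentiles
#' are mapped to 0 and 1 and values beyond them are clipped. Monotone on
#' unclipped pixels; output always within \[0, 1\]. A constant image is
#' returned unchanged with attribute `constant = TRUE`.
#'
#' @param img intensity matrix/array in \[0, 1\].
#' @param p_low,p_high percentiles in \[0, 100\], `p_low < p_high`.
#' @return stretched image, same shape.
#' @export
histogram_stretch <- function(img, p_low, p_high) {
  stopifnot(p_low >= 0, p_high <= 100, p_low < p_high)
  q <- stats::quantile(img, c(p_low, p_high) / 100, names = FALSE)
  if (q[2] <= q[1]) return(structure(img, constant = TRUE))
  out <- pmin(1, pmax(0, (img - q[1]) / (q[2] - q[1])))
  attributes(out) <- attributes(img)
  out
}

#' Class-specific augmentation plan
#'
#' An ordered list of operations, each either a horizontal flip or a
#' percentile stretch. Applying a plan of length `n` multiplies the set size
#' by `2^n`, because every operation doubles the current set (original plus
#' transformed copies, including copies of earlier outputs). The published
#' plans are `flip + 3 stretches` for the nodular class and `flip + 1
#' stretch` for the non-nodular class; the stretch percentiles are not
#' printed, so distinct defaults are used to avoid literal duplicates.
#'
#' @param class `"nodular"` or `"non_nodular"`, or `"custom"` with `ops`.
#' @param ops for `"custom"`: list of `list(op = "flip")` /
#'   `list(op = "stretch", p_low =, p_high =)` entries.
#' @return object of class `augmentation_plan`.
#' @export
augmentation_plan <- function(class = c("nodular", "non_nodular", "custom"),
                              ops = NULL) {
  class <- match.arg(class)
  if (class == "nodular")
    ops <- list(list(op = "flip"),
                list(op = "stretch", p_low = 1, p_high = 99),
                list(op = "stretch", p_low = 2, p_high = 98),
                list(op = "stretch", p_low = 5, p_high = 95))
  else if (class == "non_nodular")
    ops <- list(list(op = "flip"),
                list(op = "stretch", p_low = 2, p_high = 98))
  else if (is.null(ops)) stop("custom plan needs ops")
  for (o in ops)
    if (!o$op %in% c("flip", "stretch")) stop("unknown operation: ", o$op)
  structure(list(class = class, ops = ops), class = "augmentation_plan")
}

.apply_op <- function(img, o) {
  if (o$op == "flip") horizontal_flip(img)
  else histogram_stretch(img, o$p_low, o$p_high)
}

#' Apply an augmentation plan to an image set
#'
#' For each operation in order, the current set is extended with the
#' operation applied to every element, so `length(out) ==
#' length(images) * 2^length(plan$ops)` structurally (no deduplication, per
#' the published counts: 16 nodular crops become 256, 68 non-nodular become
#' 272). Spatial dimensions are never changed; rescaling is deliberately not
#' an available operation.
#'
#' @param images list of intensity arrays in \[0, 1\].
#' @param plan an [augmentation_plan()].
#' @return list of augmented images; each element carries a `provenance`
#'   attribute with the chain of applied operations.
#' @examples
#' imgs <- replicate(2, matrix(runif(16), 4), simplify = FALSE)
#' length(augment(imgs, augmentation_plan("non_nodular")))  # 2 * 2^2 = 8
#' @export
augment <- function(images, plan) {
  stopifnot(inherits(plan, "augmentation_plan"), is.list(images),
            length(images) >= 1)
  cur <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    attr(img, "provenance") <- paste0("src", i)
    img
  })
  for (o in plan$ops) {
    tagged <- lapply(cur, function(img) {
      out <- .apply_op(img, o)
      tag <- if (o$op == "flip") "flip"
             else sprintf("stretch(%g,%g)", o$p_low, o$p_high)
      attr(out, "provenance") <- paste(attr(img, "provenance"), tag,
                                       sep = "+")
      out
    })
    cur <- c(cur, tagged)
  }
  cur
}

#' Augmentation manifest
#'
#' @param images an [augment()] result.
#' @return data frame with one row per image: `index`, `provenance`.
#' @export
augmentation_manifest <- function(images) {
  data.frame(index = seq_along(images),
             provenance = vapply(images, function(i)
               attr(i, "provenance") %||% NA_character_, ""))
}
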