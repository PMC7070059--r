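.lvl_arch <- c("none", "present")
.lvl_collapsed <- c("none", "present", "significant")
.lvl_lumen <- c("absent", "present", "high")
.lvl_area <- c("low", "high")
.lvl_erosion_cells <- c("none", "present", "exclusive")
.lvl_loss <- c("none", "present", "significant")

.ord <- function(x, levels) match(x, levels)

#' Categorical disease features of a single CLE video frame
#'
#' The feature vocabulary of the endomicroscopy severity rubric:
#' crypt architecture integrity (acriflavine channel) and neutrophil
#' elastase probe signal (NE680 channel). Defaults describe a healthy
#' frame.
#'
#' @param healthy_crypt_fraction fraction of crypts with healthy
#'   structure, in \[0, 1\].
#' @param crypt_architecture_change `"none"` or `"present"`.
#' @param collapsed_crypts `"none"`, `"present"` or `"significant"`.
#' @param ne680_lumen NE680 signal in crypt lumen: `"absent"`,
#'   `"present"` or `"high"`.
#' @param ne680_area overall NE680-positive area: `"low"` or `"high"`.
#' @param acriflavine_unstained_fraction fraction of crypts lacking
#'   acriflavine staining, in \[0, 1\].
#' @param ne680_cells_in_erosions NE680-positive cells within erosions:
#'   `"none"`, `"present"`, or `"exclusive"` (only such cells remain).
#' @param crypt_loss `"none"`, `"present"` or `"significant"`.
#' @return object of class `frame_annotation`.
#' @examples
#' score_frame(frame_annotation())  # healthy frame scores 0
#' @export
frame_annotation <- function(healthy_crypt_fraction = 1,
                             crypt_architecture_change = "none",
                             collapsed_crypts = "none",
                             ne680_lumen = "absent",
                             ne680_area = "low",
                             acriflavine_unstained_fraction = 0,
                             ne680_cells_in_erosions = "none",
                             crypt_loss = "none") {
  chk <- function(x, levels, nm) {
    if (length(x) != 1L || !(x %in% levels)) {
      stop(sprintf("%s must be one of: %s", nm,
                   paste(levels, collapse = ", ")), call. = FALSE)
    }
    x
  }
  frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
      stop(sprintf("%s must be a fraction in [0, 1]", nm), call. = FALSE)
    }
    x
  }
  a <- list(
    healthy_crypt_fraction = frac(healthy_crypt_fraction,
                                  "healthy_crypt_fraction"),
    crypt_architecture_change = chk(crypt_architecture_change, .lvl_arch,
                                    "crypt_architecture_change"),
    collapsed_crypts = chk(collapsed_crypts, .lvl_collapsed,
                           "collapsed_crypts"),
    ne680_lumen = chk(ne680_lumen, .lvl_lumen, "ne680_lumen"),
    ne680_area = chk(ne680_area, .lvl_area, "ne680_area"),
    acriflavine_unstained_fraction = frac(acriflavine_unstained_fraction,
                                          "acriflavine_unstained_fraction"),
    ne680_cells_in_erosions = chk(ne680_cells_in_erosions,
                                  .lvl_erosion_cells,
                                  "ne680_cells_in_erosions"),
    crypt_loss = chk(crypt_loss, .lvl_loss, "crypt_loss")
  )
  if (a$crypt_architecture_change == "none" &&
      (a$collapsed_crypts != "none" || a$crypt_loss != "none")) {
    stop(paste("collapsed crypts / crypt loss imply a change in crypt",
               "architecture"), call. = FALSE)
  }
  structure(a, class = "frame_annotation")
}

#' Score one CLE frame on the 0-5 severity rubric
#'
#' Each grade's criteria are read as minimum-severity requirements and
#' the frame receives the most severe matching grade, the convention of
#' clinical severity indices (a frame that is worse than a grade's
#' description never receives a lower grade):
#'
#' * 5 - only NE680-positive cells within erosions; significant crypt
#'   loss.
#' * 4 - more than half of crypts lack acriflavine staining; high
#'   luminal NE680; NE680-positive cells within erosions.
#' * 3 - significant presence of collapsed crypts; high NE680-positive
#'   area.
#' * 2 - high NE680 signal in crypt lumen with collapsed crypts present
#'   (Table-style ">50% healthy crypt structure" describes this grade's
#'   typical appearance; frames with fewer healthy crypts are at least
#'   this severe, so the fraction does not gate the grade).
#' * 1 - any NE680 signal (luminal, area or erosion-associated) in an
#'   otherwise less affected frame.
#' * 0 - no NE680 signal.
#'
#' @param annotation a [frame_annotation()].
#' @return integer severity score 0-5.
#' @export
score_frame <- function(annotation) {
  if (!inherits(annotation, "frame_annotation")) {
    annotation <- do.call(frame_annotation, as.list(annotation))
  }
  a <- annotation
  lumen <- .ord(a$ne680_lumen, .lvl_lumen)
  collapsed <- .ord(a$collapsed_crypts, .lvl_collapsed)
  erosion <- .ord(a$ne680_cells_in_erosions, .lvl_erosion_cells)
  loss <- .ord(a$crypt_loss, .lvl_loss)
  area_high <- a$ne680_area == "high"

  if (erosion >= 3 && loss >= 3) return(5L)
  if (a$acriflavine_unstained_fraction > 0.5 && lumen >= 3 && erosion >= 2) {
    return(4L)
  }
  if (collapsed >= 3 && area_high) return(3L)
  if (lumen >= 3 && collapsed >= 2) return(2L)
  if (lumen >= 2 || area_high || erosion >= 2) return(1L)
  0L
}

#' Aggregate frame scores to a per-animal severity score
#'
#' Default aggregation is the modal frame score with ties broken toward
#' the higher score; `"max"` and `"median"` (ties also upward) are
#' available. At least three videos per animal are expected; fewer
#' produce a warning, not an error.
#'
#' @param frames list of [frame_annotation()] objects (or a single one).
#' @param method `"mode"`, `"max"` or `"median"`.
#' @param animal_id identifier carried into the result.
#' @return object of class `animal_score`: `animal_id`, `frame_scores`,
#'   `score`, `method`.
#' @examples
#' fr <- replicate(3, frame_annotation(ne680_lumen = "present"),
#'                 simplify = FALSE)
#' score_animal(fr)$score
#' @export
score_animal <- function(frames, method = c("mode", "max", "median"),
                         animal_id = "animal") {
  method <- match.arg(method)
  if (inherits(frames, "frame_annotation")) frames <- list(frames)
  if (length(frames) == 0L) stop("no frames to score", call. = FALSE)
  if (length(frames) < 3L) {
    warning("fewer than 3 frames for ", animal_id,
            "; per-animal score may be unstable", call. = FALSE)
  }
  sc <- vapply(frames, score_frame, integer(1))
  agg <- switch(method,
    mode = {
      tab <- table(sc)
      winners <- as.integer(names(tab)[tab == max(tab)])
      max(winners)  # tie toward the higher score
    },
    max = max(sc),
    median = as.integer(ceiling(stats::median(sc)))
  )
  structure(
    list(animal_id = animal_id, frame_scores = sc, score = as.integer(agg),
         method = method),
    class = "animal_score"
  )
}
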