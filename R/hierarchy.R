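#' Build a balanced two-level class/superclass hierarchy
#'
#' Constructs the label structure used throughout the package: `C = n_superclasses
#' * classes_per_superclass` fine classes, each nested in exactly one
#' superclass. Class `k` (0-based) belongs to superclass
#' `floor(k / classes_per_superclass)`, mirroring datasets such as CIFAR-100
#' where 100 object classes nest in 20 balanced categorical superclasses.
#'
#' @param n_superclasses Number of superclasses (>= 2).
#' @param classes_per_superclass Number of classes nested in each superclass (>= 1).
#' @return A `class_hierarchy` object: a tibble with integer columns
#'   `class_id` (0..C-1) and `superclass_id` (0..S-1), plus attributes
#'   `n_classes` and `n_superclasses`.
#' @examples
#' h <- make_hierarchy(5, 4)
#' superclass_of(h, c(0, 7, 19))
#' @export
make_hierarchy <- function(n_superclasses, classes_per_superclass) {
  n_superclasses <- check_count(n_superclasses, "n_superclasses", min = 2L)
  classes_per_superclass <- check_count(classes_per_superclass, "classes_per_superclass")
  n_classes <- n_superclasses * classes_per_superclass
  h <- tibble::tibble(
    class_id = 0:(n_classes - 1L),
    superclass_id = as.integer((0:(n_classes - 1L)) %/% classes_per_superclass)
  )
  structure(h,
            class = c("class_hierarchy", class(h)),
            n_classes = n_classes,
            n_superclasses = n_superclasses)
}

#' @export
print.class_hierarchy <- function(x, ...) {
  cat(sprintf("<class_hierarchy> %d classes in %d superclasses\n",
              attr(x, "n_classes"), attr(x, "n_superclasses")))
  NextMethod()
}

#' Map class identifiers to superclass identifiers
#'
#' @param hierarchy A `class_hierarchy`.
#' @param class_ids Integer vector of class identifiers (0-based).
#' @return Integer vector of superclass identifiers, same length.
#' @export
superclass_of <- function(hierarchy, class_ids) {
  stopifnot(inherits(hierarchy, "class_hierarchy"))
  idx <- match(as.integer(class_ids), hierarchy$class_id)
  if (anyNA(idx)) {
    abort("Some `class_ids` are not present in the hierarchy.",
          class = "degensim_invalid_argument")
  }
  hierarchy$superclass_id[idx]
}

n_classes <- function(hierarchy) attr(hierarchy, "n_classes")
n_superclasses <- function(hierarchy) attr(hierarchy, "n_superclasses")

validate_hierarchy <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "class_hierarchy"))
  if (anyDuplicated(hierarchy$class_id) > 0L) {
    abort("Duplicate class ids in hierarchy.", class = "degensim_invalid_argument")
  }
  tab <- table(hierarchy$superclass_id)
  if (length(tab) < 2L || any(tab < 1L)) {
    abort("Hierarchy needs >= 2 superclasses, each with >= 1 class.",
          class = "degensim_invalid_argument")
  }
  invisible(hierarchy)
}
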