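## broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with one row per hyperparameter point.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$table

#' @rdname tidy.cv_result
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::mutate(x$winner, folds = x$cv$folds, repeats = x$cv$repeats,
                seed = x$seed)
}

#' Tidy a trained model bundle
#'
#' `tidy()` returns the CV table the winner was chosen from;
#' `glance()` a one-row summary of the fitted bundle.
#'
#' @param x A `cyp_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cyp_model
#' @export
tidy.cyp_model <- function(x, ...) x$cv_result$table

#' @rdname tidy.cyp_model
#' @method glance cyp_model
#' @export
glance.cyp_model <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    n_features = length(x$features),
    cv_accuracy = x$cv_result$winner$mean_accuracy,
    cv_sd = x$cv_result$winner$sd_accuracy,
    seed = x$seed,
    !!!x$params
  )
}

#' Tidy an importance profile
#'
#' @param x An `importance_profile`.
#' @param ... Unused.
#' @return Tibble `descriptor`, `importance`, `rank`.
#' @method tidy importance_profile
#' @export
tidy.importance_profile <- function(x, ...) {
  tibble::as_tibble(x) |> dplyr::mutate(rank = dplyr::row_number())
}

#' Tidy a confusion matrix
#'
#' `tidy()` returns the four counts; `glance()` the derived metrics.
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(cell = c("tp", "fn", "tn", "fp"),
                 n = c(x$tp, x$fn, x$tn, x$fp))
}

#' @rdname tidy.confusion_matrix
#' @method glance confusion_matrix
#' @export
glance.confusion_matrix <- function(x, ...) metrics(x)

#' Tidy a screening report
#'
#' `tidy()` returns the per-candidate table; `glance()` the cascade
#' counts in wide form.
#'
#' @param x A `screen_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy screen_report
#' @export
tidy.screen_report <- function(x, ...) x$candidates

#' @rdname tidy.screen_report
#' @method glance screen_report
#' @export
glance.screen_report <- function(x, ...) {
  tidyr::pivot_wider(x$counts, names_from = "stage", values_from = "n")
}
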