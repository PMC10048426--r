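# Price factors and adulteration detection for mixed grain samples.
# Each variety i contributes price p_i (per kg) weighted by the volume proxy
# L_i * l_i^2 (mean grain length times width squared); a mixture's price
# factor is the count-weighted per-grain average of p_i * L_i * l_i^2.

#' Per-variety price table
#'
#' @param variety Character vector of variety codes.
#' @param price_per_kg Positive prices (currency per kg).
#' @param mean_length,mean_width Mean grain dimensions (same unit per
#'   variety, e.g. pixels at a fixed scale); length must be >= width > 0.
#' @return Tibble with class `price_table`.
#' @export
price_table <- function(variety, price_per_kg, mean_length, mean_width) {
  if (any(price_per_kg <= 0)) {
    abort_grainscan("prices must be > 0", "grainscan_invalid_parameter")
  }
  if (any(mean_width <= 0) || any(mean_length < mean_width)) {
    abort_grainscan("need mean_length >= mean_width > 0",
                    "grainscan_invalid_parameter")
  }
  structure(
    tibble(variety = as.character(variety), price_per_kg = price_per_kg,
           mean_length = mean_length, mean_width = mean_width),
    class = c("price_table", class(tibble())))
}

#' Synthetic default price table
#'
#' Prices are synthetic stand-ins (currency per kg) with the long-grain
#' basmati types priced above the short kolam types; grain dimensions come
#' from the default synthetic variety profiles.
#'
#' @param varieties Named list of profiles, default [default_varieties()].
#' @return A [price_table()].
#' @export
default_price_table <- function(varieties = default_varieties()) {
  prices <- c(BM = 120, KB = 95, TB = 80, TKB = 60, EK = 55, HK = 50,
              WK = 45, SM = 65)
  nm <- names(varieties)
  price_table(
    variety = nm,
    price_per_kg = as.numeric(prices[nm]),
    mean_length = vapply(varieties, `[[`, numeric(1), "length_mean"),
    mean_width = vapply(varieties, `[[`, numeric(1), "width_mean")
  )
}

#' Estimate a price table's grain dimensions from a feature table
#'
#' Replaces `mean_length`/`mean_width` by the per-variety means of the
#' fitted-ellipse `length`/`width` features.
#'
#' @param prices A [price_table()].
#' @param feature_table Labelled feature table with `length` and `width`
#'   columns.
#' @return Updated [price_table()].
#' @export
price_table_from_features <- function(prices, feature_table) {
  dims <- feature_table |>
    dplyr::group_by(.data$variety) |>
    dplyr::summarise(mean_length = mean(.data$length),
                     mean_width = mean(.data$width), .groups = "drop")
  out <- prices |>
    dplyr::select(-"mean_length", -"mean_width") |>
    dplyr::inner_join(dims, by = "variety")
  price_table(out$variety, out$price_per_kg, out$mean_length, out$mean_width)
}

normalise_counts <- function(counts, prices) {
  if (is.data.frame(counts)) {
    counts <- setNames(counts$n, counts$variety)
  }
  if (is.null(names(counts)) || length(counts) == 0L || sum(counts) == 0) {
    abort_grainscan("counts must be a non-empty named vector with a positive sum",
                    "grainscan_empty_mixture")
  }
  missing <- setdiff(names(counts), prices$variety)
  if (length(missing) > 0L) {
    abort_grainscan(sprintf("no price for variety: %s",
                            paste(missing, collapse = ", ")),
                    "grainscan_missing_price")
  }
  counts
}

per_variety_value <- function(prices) {
  setNames(prices$price_per_kg * prices$mean_length * prices$mean_width^2,
           prices$variety)
}

#' Mixture price factor
#'
#' The count-weighted average of `p_i * L_i * l_i^2` over varieties, i.e.
#' the per-grain price proxy of the mixture. With actual per-variety counts
#' this is the actual price factor; with predicted counts, the predicted
#' price factor. `per_grain = FALSE` returns the summed (not averaged)
#' convention instead.
#'
#' @param counts Named per-variety counts (or a tibble with `variety`, `n`).
#' @param prices A [price_table()].
#' @param per_grain Divide by the total count (default TRUE).
#' @return One number.
#' @export
price_factor <- function(counts, prices, per_grain = TRUE) {
  counts <- normalise_counts(counts, prices)
  v <- per_variety_value(prices)[names(counts)]
  total <- sum(v * counts)
  if (per_grain) total / sum(counts) else total
}

#' Price factor of the unadulterated reference
#'
#' Uses only the majority variety (argmax count; ties go to the
#' higher-priced variety): the per-grain value the sample would have were it
#' pure.
#'
#' @inheritParams price_factor
#' @return One number (`p_j * L_j * l_j^2`, times the total count when
#'   `per_grain = FALSE`).
#' @export
price_factor_unadulterated <- function(counts, prices, per_grain = TRUE) {
  counts <- normalise_counts(counts, prices)
  v <- per_variety_value(prices)
  mx <- max(counts)
  cand <- names(counts)[counts == mx]
  if (length(cand) > 1L) {
    pk <- setNames(prices$price_per_kg, prices$variety)[cand]
    cand <- cand[which.max(pk)]
  }
  if (per_grain) v[[cand]] else v[[cand]] * sum(counts)
}

#' Adulteration report for a predicted mixture
#'
#' Converts per-grain variety predictions (and, when available, true
#' varieties) into the three price factors, the percent price error
#' `100 |predicted - actual| / actual`, the minority detection rate (the
#' fraction of true minority-variety grains predicted as any non-majority
#' variety) and an adulteration flag raised when the predicted and
#' unadulterated factors differ by more than `margin` (relative).
#'
#' @param predictions Character vector of predicted varieties, one per
#'   grain.
#' @param truth Optional character vector of true varieties.
#' @param prices A [price_table()].
#' @param margin Relative difference treated as significant (default 0.05).
#' @param per_grain Price-factor convention, see [price_factor()].
#' @return A `price_report` list; `tidy()` gives a one-row tibble.
#' @export
adulteration_report <- function(predictions, truth = NULL, prices,
                                margin = 0.05, per_grain = TRUE) {
  predictions <- as.character(predictions)
  if (length(predictions) == 0L) {
    abort_grainscan("no predicted grains", "grainscan_empty_mixture")
  }
  M <- table(predictions)
  M <- setNames(as.numeric(M), names(M))
  predicted_pf <- price_factor(M, prices, per_grain)

  actual_pf <- NA_real_
  price_error_pct <- NA_real_
  detection_rate <- NA_real_
  if (!is.null(truth)) {
    truth <- as.character(truth)
    if (length(truth) != length(predictions)) {
      abort_grainscan("truth and predictions differ in length",
                      "grainscan_invalid_input")
    }
    N <- table(truth)
    N <- setNames(as.numeric(N), names(N))
    actual_pf <- price_factor(N, prices, per_grain)
    price_error_pct <- 100 * abs(predicted_pf - actual_pf) / actual_pf
    unadult_pf <- price_factor_unadulterated(N, prices, per_grain)
    majority <- names(N)[which.max(N)]
    minority <- truth != majority
    detection_rate <- if (any(minority)) {
      mean(predictions[minority] != majority)
    } else NA_real_
  } else {
    unadult_pf <- price_factor_unadulterated(M, prices, per_grain)
  }
  structure(
    list(
      actual_pf = actual_pf, predicted_pf = predicted_pf,
      unadulterated_pf = unadult_pf,
      price_error_pct = price_error_pct,
      detection_rate = detection_rate,
      adulteration_flag =
        abs(predicted_pf - unadult_pf) / unadult_pf > margin,
      margin = margin, per_grain = per_grain,
      counts_predicted = M,
      counts_actual = if (is.null(truth)) NULL else N
    ),
    class = "price_report"
  )
}

#' @export
print.price_report <- function(x, ...) {
  cat(sprintf(
    "price factors: actual %s | predicted %.2f | unadulterated %.2f\n",
    ifelse(is.na(x$actual_pf), "n/a", sprintf("%.2f", x$actual_pf)),
    x$predicted_pf, x$unadulterated_pf))
  if (!is.na(x$price_error_pct)) {
    cat(sprintf("price error %.1f%% | minority detection rate %s\n",
                x$price_error_pct,
                ifelse(is.na(x$detection_rate), "n/a",
                       sprintf("%.2f", x$detection_rate))))
  }
  cat(sprintf("adulteration flag: %s (margin %.0f%%)\n",
              x$adulteration_flag, 100 * x$margin))
  invisible(x)
}

#' @rdname adulteration_report
#' @param x A `price_report`.
#' @param ... Ignored.
#' @export
tidy.price_report <- function(x, ...) {
  tibble(
    actual_pf = x$actual_pf, predicted_pf = x$predicted_pf,
    unadulterated_pf = x$unadulterated_pf,
    price_error_pct = x$price_error_pct,
    detection_rate = x$detection_rate,
    adulteration_flag = x$adulteration_flag
  )
}
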