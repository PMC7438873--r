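#' Q-matrix used by the packaged simulation design
#'
#' A complex-structure Q-matrix with 30 items and 3 attributes: items cycle
#' through five blocks of six, each block holding one single-attribute item per
#' attribute followed by the three possible two-attribute items, so every item
#' measures at most two attributes and every attribute is measured by exactly
#' 15 items.
#'
#' @return A tibble with an `item` column and one 0/1 column per attribute
#'   (`A1`, `A2`, `A3`).
#' @export
#' @examples
#' qmatrix_design()
qmatrix_design <- function() {
  block <- rbind(
    c(1, 0, 0),
    c(0, 1, 0),
    c(0, 0, 1),
    c(1, 1, 0),
    c(1, 0, 1),
    c(0, 1, 1)
  )
  q <- do.call(rbind, rep(list(block), 5))
  colnames(q) <- paste0("A", 1:3)
  dplyr::bind_cols(tibble::tibble(item = seq_len(nrow(q))), tibble::as_tibble(q))
}

q_attr_names <- function(qmatrix) setdiff(names(qmatrix), "item")

# numeric I x K matrix view of a Q-matrix tibble
q_matrix <- function(qmatrix) {
  m <- as.matrix(qmatrix[q_attr_names(qmatrix)])
  storage.mode(m) <- "double"
  rownames(m) <- qmatrix$item
  m
}

#' Validate a Q-matrix
#'
#' Checks that every entry is 0/1 and every item measures at least one
#' attribute. The packaged design additionally caps items at two attributes;
#' items measuring three or more attributes are rejected because higher-order
#' interaction terms are not supported.
#'
#' @param qmatrix A tibble with an `item` column and 0/1 attribute columns.
#' @return `qmatrix`, invisibly, if valid; otherwise an error.
#' @export
validate_qmatrix <- function(qmatrix) {
  if (!is.data.frame(qmatrix) || !"item" %in% names(qmatrix)) {
    abort("`qmatrix` must be a data frame with an `item` column.")
  }
  if (length(q_attr_names(qmatrix)) < 1) {
    abort("`qmatrix` must have at least one attribute column.")
  }
  m <- q_matrix(qmatrix)
  if (!all(m %in% c(0, 1))) {
    abort("Q-matrix entries must all be 0 or 1.")
  }
  if (any(rowSums(m) < 1)) {
    abort("Every item must measure at least one attribute.")
  }
  if (any(rowSums(m) > 2)) {
    abort("Items measuring more than two attributes are not supported.")
  }
  if (anyDuplicated(qmatrix$item)) {
    abort("Item identifiers must be unique.")
  }
  invisible(qmatrix)
}

#' Read or write a Q-matrix as CSV
#'
#' Header-bearing CSV with rows as items: an `item` column plus one 0/1 column
#' per attribute.
#'
#' @param path File path.
#' @param qmatrix A Q-matrix tibble.
#' @return `read_qmatrix()` returns a validated Q-matrix tibble;
#'   `write_qmatrix()` returns `qmatrix` invisibly.
#' @export
read_qmatrix <- function(path) {
  q <- readr::read_csv(path, show_col_types = FALSE)
  validate_qmatrix(q)
  q
}

#' @rdname read_qmatrix
#' @export
write_qmatrix <- function(qmatrix, path) {
  validate_qmatrix(qmatrix)
  readr::write_csv(qmatrix, path)
  invisible(qmatrix)
}

#' Construct an LCDM item-parameter table
#'
#' Builds the tidy item-parameter table for a Q-matrix: one `intercept` row per
#' item, one `main` row per (item, measured attribute), and one `interaction`
#' row per two-attribute item. Defaults are the fixed values of the packaged
#' simulation design: intercept -1.5 (correct-response probability 0.18 with no
#' mastery), main effect 1.5 (probability 0.50 after mastering a
#' single measured attribute), interaction 0.5 (probability 0.88 after
#' mastering both attributes of a two-attribute item).
#'
#' @param qmatrix A Q-matrix tibble (default [qmatrix_design()]).
#' @param intercept,main,interaction Parameter values on the log-odds scale;
#'   scalars are recycled across items.
#' @return A tibble with columns `item`, `parameter_type`
#'   (`intercept`/`main`/`interaction`), `attributes` (e.g. `"A1"` or
#'   `"A1:A2"`, `NA` for intercepts) and `value`.
#' @export
#' @examples
#' item_parameters(qmatrix_design())
item_parameters <- function(qmatrix = qmatrix_design(),
                            intercept = -1.5, main = 1.5, interaction = 0.5) {
  validate_qmatrix(qmatrix)
  m <- q_matrix(qmatrix)
  attrs <- q_attr_names(qmatrix)
  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    meas <- which(m[i, ] == 1)
    out <- tibble::tibble(
      item = qmatrix$item[i],
      parameter_type = c("intercept", rep("main", length(meas))),
      attributes = c(NA_character_, attrs[meas]),
      value = c(rep_len(intercept, nrow(m))[i],
                rep(rep_len(main, nrow(m))[i], length(meas)))
    )
    if (length(meas) == 2) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        item = qmatrix$item[i],
        parameter_type = "interaction",
        attributes = paste(attrs[meas], collapse = ":"),
        value = rep_len(interaction, nrow(m))[i]
      ))
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Validate an item-parameter table against a Q-matrix
#'
#' Checks structural consistency (parameters exist exactly for the attributes
#' the Q-matrix assigns) and, by default, the monotonicity constraints that
#' identify the LCDM: main effects must be nonnegative and each interaction at
#' least `-min(main effects of its pair)`, so that mastering an attribute never
#' lowers the success probability.
#'
#' @param params An item-parameter tibble (see [item_parameters()]).
#' @param qmatrix The matching Q-matrix.
#' @param enforce_monotonicity Set `FALSE` to skip the inequality constraints
#'   (research use only; the sampler always enforces them).
#' @return `params`, invisibly, if valid.
#' @export
validate_item_parameters <- function(params, qmatrix,
                                     enforce_monotonicity = TRUE) {
  validate_qmatrix(qmatrix)
  needed <- c("item", "parameter_type", "attributes", "value")
  if (!all(needed %in% names(params))) {
    abort(paste0("`params` must have columns ",
                 paste(needed, collapse = ", "), "."))
  }
  ref <- item_parameters(qmatrix)
  key <- function(x) paste(x$item, x$parameter_type, x$attributes, sep = "\r")
  if (!setequal(key(ref), key(params)) || nrow(ref) != nrow(params)) {
    extra <- setdiff(key(params), key(ref))
    if (length(extra) > 0) {
      abort("Parameter present for an item/attribute combination the Q-matrix does not assign.")
    }
    abort("Item-parameter table does not cover every Q-matrix assignment exactly once.")
  }
  if (enforce_monotonicity) {
    mains <- params[params$parameter_type == "main", ]
    if (any(mains$value < 0)) {
      abort("Main effects must be >= 0 (monotonicity constraint).")
    }
    ints <- params[params$parameter_type == "interaction", ]
    for (i in seq_len(nrow(ints))) {
      pair_mains <- mains$value[mains$item == ints$item[i]]
      if (ints$value[i] < -min(pair_mains)) {
        abort("Interactions must be >= -min(main effects of the pair) (monotonicity constraint).")
      }
    }
  }
  invisible(params)
}

#' Read or write item parameters as CSV
#'
#' CSV with columns `item`, `parameter_type` (`intercept`/`main`/
#' `interaction`), `attributes` and `value`.
#'
#' @param path File path.
#' @param params An item-parameter tibble.
#' @return `read_item_parameters()` returns the tibble; `write_item_parameters()`
#'   returns `params` invisibly.
#' @export
read_item_parameters <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    item = readr::col_integer(),
                    parameter_type = readr::col_character(),
                    attributes = readr::col_character(),
                    value = readr::col_double()
                  ))
}

#' @rdname read_item_parameters
#' @export
write_item_parameters <- function(params, path) {
  readr::write_csv(params, path)
  invisible(params)
}

# Compile a tidy item-parameter table into dense arrays for fast evaluation:
# lambda0 (I), Lmain (I x K, zero where q = 0), and per-item interaction value
# with the attribute pair (k1 < k2; 0/NA for single-attribute items).
ip_compile <- function(params, qmatrix, check = TRUE) {
  if (check) validate_item_parameters(params, qmatrix,
                                      enforce_monotonicity = FALSE)
  attrs <- q_attr_names(qmatrix)
  K <- length(attrs)
  items <- qmatrix$item
  I <- length(items)
  lambda0 <- numeric(I)
  Lmain <- matrix(0, I, K, dimnames = list(items, attrs))
  int_val <- numeric(I)
  k1 <- rep(NA_integer_, I)
  k2 <- rep(NA_integer_, I)
  idx <- match(params$item, items)
  for (r in seq_len(nrow(params))) {
    i <- idx[r]
    type <- params$parameter_type[r]
    if (type == "intercept") {
      lambda0[i] <- params$value[r]
    } else if (type == "main") {
      Lmain[i, match(params$attributes[r], attrs)] <- params$value[r]
    } else {
      pair <- sort(match(strsplit(params$attributes[r], ":")[[1]], attrs))
      k1[i] <- pair[1]
      k2[i] <- pair[2]
      int_val[i] <- params$value[r]
    }
  }
  list(lambda0 = lambda0, Lmain = Lmain, int_val = int_val,
       k1 = k1, k2 = k2, items = items, attrs = attrs, K = K, I = I)
}

# LCDM linear predictor: alpha is an n x K 0/1 matrix, returns n x I logits.
lcdm_eta <- function(alpha, ipm) {
  eta <- alpha %*% t(ipm$Lmain)
  eta <- sweep(eta, 2, ipm$lambda0, "+")
  two <- which(!is.na(ipm$k1))
  if (length(two) > 0) {
    eta[, two] <- eta[, two] +
      (alpha[, ipm$k1[two], drop = FALSE] * alpha[, ipm$k2[two], drop = FALSE]) *
        rep(ipm$int_val[two], each = nrow(alpha))
  }
  eta
}

check_profile <- function(profile, K) {
  if (length(profile) != K) {
    abort(sprintf("`profile` has length %d but the Q-matrix has %d attributes.",
                  length(profile), K))
  }
  if (!all(profile %in% c(0, 1))) {
    abort("`profile` entries must be 0 or 1.")
  }
  as.numeric(profile)
}

#' LCDM correct-response probability
#'
#' Probability of a correct response to each item given an attribute profile:
#' the inverse logit of the item intercept plus the main effects of mastered
#' measured attributes plus the interaction when both attributes of a
#' two-attribute item are mastered. Attributes the item does not measure never
#' affect the result.
#'
#' @param params Item-parameter tibble (see [item_parameters()]).
#' @param qmatrix The matching Q-matrix.
#' @param profile 0/1 vector of length K (attribute mastery indicators).
#' @param items Optional subset of item identifiers.
#' @return A tibble with columns `item` and `probability` (each strictly in
#'   (0, 1) for finite parameters).
#' @export
#' @examples
#' q <- qmatrix_design()
#' ip <- item_parameters(q)
#' response_probability(ip, q, c(0, 0, 0), items = 1) # 0.18
#' response_probability(ip, q, c(1, 1, 0), items = 4) # 0.88
response_probability <- function(params, qmatrix, profile, items = NULL) {
  validate_qmatrix(qmatrix)
  ipm <- ip_compile(params, qmatrix)
  profile <- check_profile(profile, ipm$K)
  eta <- unname(drop(lcdm_eta(matrix(profile, 1), ipm)))
  out <- tibble::tibble(item = ipm$items, probability = plogis(eta))
  if (!is.null(items)) {
    if (!all(items %in% out$item)) abort("Unknown item identifier in `items`.")
    out <- out[match(items, out$item), ]
  }
  out
}

# All 2^K binary profiles in canonical order: attribute 1 is the
# fastest-varying bit, so class c (1-based) has alpha_k = bit (c-1) >> (k-1).
all_profiles <- function(K) {
  cls <- 0:(2^K - 1)
  m <- sapply(seq_len(K), function(k) bitwAnd(bitwShiftR(cls, k - 1L), 1L))
  matrix(as.numeric(m), ncol = K)
}

#' Per-latent-class response probability table
#'
#' Enumerates all `2^K` attribute profiles in canonical order (attribute 1 is
#' the fastest-varying bit: class 1 is all-zero, class 2 masters attribute 1
#' only, ...) and evaluates the LCDM response probability of every item for
#' every class.
#'
#' @inheritParams response_probability
#' @param max_attributes Refuse enumeration beyond this many attributes
#'   (default 10, i.e. 1024 classes).
#' @return A tibble with columns `class` (1-based canonical index), `profile`
#'   (e.g. `"110"`, attribute 1 first), one `alpha_*` indicator column per
#'   attribute, `item` and `probability`.
#' @export
class_probability_table <- function(params, qmatrix, items = NULL,
                                    max_attributes = 10) {
  validate_qmatrix(qmatrix)
  ipm <- ip_compile(params, qmatrix)
  if (ipm$K > max_attributes) {
    abort(sprintf("K = %d exceeds `max_attributes` = %d.", ipm$K, max_attributes))
  }
  prof <- all_profiles(ipm$K)
  p <- plogis(lcdm_eta(prof, ipm))  # 2^K x I
  keep <- if (is.null(items)) ipm$items else items
  if (!all(keep %in% ipm$items)) abort("Unknown item identifier in `items`.")
  cols <- match(keep, ipm$items)
  base <- tibble::tibble(
    class = seq_len(nrow(prof)),
    profile = apply(prof, 1, paste, collapse = "")
  )
  alpha_tbl <- tibble::as_tibble(prof, .name_repair = ~ paste0("alpha_", ipm$attrs))
  base <- dplyr::bind_cols(base, alpha_tbl)
  tidyr::expand_grid(base, tibble::tibble(item = keep)) |>
    dplyr::arrange(.data$item, .data$class) |>
    dplyr::mutate(probability = as.vector(p[, cols, drop = FALSE]))
}

#' Reduce LCDM items to their DINA submodel
#'
#' Sets the main effects of two-attribute items to zero, leaving intercept and
#' interaction: the response probability then jumps only when *all* measured
#' attributes are mastered (deterministic-input noisy-and-gate behaviour).
#' Single-attribute items have no DINA reduction distinct from the LCDM and are
#' rejected when requested explicitly.
#'
#' @inheritParams response_probability
#' @param items Items to reduce; defaults to every multi-attribute item.
#' @return The item-parameter tibble with the selected main effects zeroed.
#' @export
reduce_to_dina <- function(params, qmatrix, items = NULL) {
  validate_qmatrix(qmatrix)
  multi <- qmatrix$item[rowSums(q_matrix(qmatrix)) >= 2]
  if (is.null(items)) {
    items <- multi
  } else if (!all(items %in% multi)) {
    abort("DINA reduction is only defined for items measuring >= 2 attributes.")
  }
  out <- params
  sel <- out$item %in% items & out$parameter_type == "main"
  out$value[sel] <- 0
  out
}
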