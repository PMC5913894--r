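VALID_OBJ_KINDS <- c("LTCP", "mean", "EUD", "maximum", "dose-volume")

#' Load a wish-list configuration file
#'
#' A wish-list is the declarative contract of prioritized planning: a short
#' list of hard maximum-dose constraints that any plan must satisfy, plus an
#' ordered list of objectives, each with a priority, a cost-function kind and
#' a goal value, processed from priority 1 downward by the lexicographic
#' optimizer. Files are YAML mappings; dose limits and goals may be given in
#' Gy or as `{percent_of_prescription: p}`. The packaged default
#' (`default_wishlist()`) is the gastric wish-list: three maximum-dose
#' constraints (PTV and patient at 105% of the prescription, a 39 mm PTV
#' shell at 50%) and eleven objective rows at priorities 1-9 (PTV LTCP with
#' goal 0.4; shell/skin maximum-dose falloff; kidney and liver mean dose;
#' heart and cord EUD; kidney, liver and lung dose-volume goals).
#'
#' @param path path to a YAML wish-list file.
#' @return An object of class `wishlist`.
#' @seealso [resolve_limits()], [write_wishlist()], [wishlist_table()]
#' @export
load_wishlist <- function(path) {
  if (!file.exists(path)) stop("wish-list file not found: ", path)
  raw <- yaml::read_yaml(path)
  as_wishlist(raw)
}

#' @rdname load_wishlist
#' @export
default_wishlist <- function() {
  load_wishlist(system.file("extdata", "gastric_wishlist.yaml",
                            package = "wishplan", mustWork = TRUE))
}

as_wishlist <- function(raw) {
  for (f in c("prescription", "constraints", "objectives"))
    if (is.null(raw[[f]])) stop("wish-list is missing the '", f, "' block")
  pres <- raw$prescription
  if (is.null(pres$dose_gy) || pres$dose_gy <= 0)
    stop("prescription dose_gy must be positive")
  if (is.null(pres$n_fractions) || pres$n_fractions < 1)
    stop("prescription n_fractions must be >= 1")
  relax <- if (is.null(raw$relaxation)) 0.03 else raw$relaxation
  if (relax < 0) stop("relaxation must be >= 0")

  cons <- lapply(seq_along(raw$constraints), function(i) {
    cn <- raw$constraints[[i]]
    lab <- sprintf("constraint %d (%s)", i, cn$volume %||% "?")
    if (is.null(cn$volume)) stop(lab, ": missing 'volume'")
    if (!identical(cn$kind, "maximum"))
      stop(lab, ": unknown constraint kind '", cn$kind, "'")
    cn$limit <- check_dose_spec(cn$limit, lab, "limit")
    cn
  })

  objs <- lapply(seq_along(raw$objectives), function(i) {
    ob <- raw$objectives[[i]]
    lab <- sprintf("objective %d (%s)", i, ob$volume %||% "?")
    if (is.null(ob$volume)) stop(lab, ": missing 'volume'")
    if (is.null(ob$priority) || ob$priority < 1)
      stop(lab, ": priority must be a positive integer")
    if (is.null(ob$kind) || !ob$kind %in% VALID_OBJ_KINDS)
      stop(lab, ": unknown objective kind '", ob$kind, "'")
    if (is.null(ob$params)) ob$params <- list()
    if (ob$kind == "LTCP") {
      if (is.null(ob$params$Dp) || is.null(ob$params$alpha))
        stop(lab, ": LTCP needs params Dp and alpha")
      if (is.null(ob$goal) || ob$goal <= 0)
        stop(lab, ": goal must be positive")
    } else if (ob$kind == "EUD") {
      if (is.null(ob$params$k))
        stop(lab, ": EUD needs param k")
      if (ob$params$k < 1) stop(lab, ": EUD k must be >= 1")
      ob$goal <- check_dose_spec(ob$goal, lab, "goal")
    } else if (ob$kind == "dose-volume") {
      if (is.null(ob$params$threshold))
        stop(lab, ": dose-volume needs param 'threshold'")
      ob$params$threshold <- check_dose_spec(ob$params$threshold, lab,
                                             "threshold")
      if (is.null(ob$goal) || !is.numeric(ob$goal) ||
          ob$goal <= 0 || ob$goal > 100)
        stop(lab, ": dose-volume goal must be a volume percent in (0, 100]")
    } else {  # mean, maximum: dose goals
      ob$goal <- check_dose_spec(ob$goal, lab, "goal")
    }
    ob
  })
  # stable sort: priority order, listed order within equal priority
  pr <- vapply(objs, function(o) as.numeric(o$priority), 0)
  objs <- objs[order(pr)]

  structure(list(prescription = list(dose_gy = pres$dose_gy,
                                     n_fractions = as.integer(pres$n_fractions)),
                 relaxation = relax, constraints = cons, objectives = objs),
            class = "wishlist")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a dose quantity is either a positive Gy number or a
# list(percent_of_prescription = p); validated, returned unchanged
check_dose_spec <- function(x, lab, what) {
  if (is.null(x)) stop(lab, ": missing ", what)
  if (is.numeric(x)) {
    if (x <= 0) stop(lab, ": ", what, " must be positive")
    return(x)
  }
  if (is.list(x) && !is.null(x$percent_of_prescription)) {
    if (x$percent_of_prescription <= 0)
      stop(lab, ": ", what, " percent must be positive")
    return(x)
  }
  stop(lab, ": ", what,
       " must be Gy or {percent_of_prescription: p}")
}

#' Resolve percent-of-prescription limits to absolute Gy
#'
#' Converts every `{percent_of_prescription: p}` limit, goal or threshold in
#' the wish-list to `p/100 * prescription`. Idempotent: already-resolved
#' values pass through unchanged. The original specification is kept in a
#' `display` attribute so the wish-list can be rendered back as printed.
#'
#' @param w a [load_wishlist()] result.
#' @return The wish-list with all dose quantities as numeric Gy.
#' @export
resolve_limits <- function(w) {
  stopifnot(inherits(w, "wishlist"))
  Dp <- w$prescription$dose_gy
  res <- function(x) {
    if (is.numeric(x)) return(x)
    out <- x$percent_of_prescription / 100 * Dp
    attr(out, "display") <- sprintf("%g%% of Dp", x$percent_of_prescription)
    out
  }
  w$constraints <- lapply(w$constraints, function(cn) {
    cn$limit <- res(cn$limit); cn
  })
  w$objectives <- lapply(w$objectives, function(ob) {
    if (ob$kind %in% c("mean", "maximum", "EUD")) ob$goal <- res(ob$goal)
    if (ob$kind == "dose-volume")
      ob$params$threshold <- res(ob$params$threshold)
    ob
  })
  w$resolved <- TRUE
  w
}

#' Write a wish-list back to YAML
#'
#' @param w a `wishlist`.
#' @param path output file path.
#' @return `path`, invisibly. `load_wishlist(write_wishlist(w, p))` gives a
#'   wish-list equal to `w`.
#' @export
write_wishlist <- function(w, path) {
  stopifnot(inherits(w, "wishlist"))
  out <- list(prescription = w$prescription,
              relaxation = w$relaxation,
              constraints = lapply(w$constraints, strip_attrs),
              objectives = lapply(w$objectives, strip_attrs))
  yaml::write_yaml(out, path)
  invisible(path)
}

strip_attrs <- function(x) {
  if (is.list(x)) return(lapply(x, strip_attrs))
  attributes(x) <- NULL
  x
}

#' Render a wish-list as a table
#'
#' One row per constraint and objective, in wish-list order, with the goal or
#' limit shown as printed in the configuration (percent-of-prescription kept
#' symbolic). Used for golden-file comparison against the published gastric
#' wish-list.
#'
#' @param w a `wishlist` (resolved or not).
#' @return data.frame with columns `block`, `priority`, `volume`, `type`,
#'   `goal`, `parameters`.
#' @export
wishlist_table <- function(w) {
  stopifnot(inherits(w, "wishlist"))
  fmt <- function(x) {
    if (is.list(x)) sprintf("%g%% of Dp", x$percent_of_prescription)
    else if (!is.null(attr(x, "display"))) attr(x, "display")
    else sprintf("%g Gy", x)
  }
  crow <- lapply(w$constraints, function(cn)
    data.frame(block = "constraint", priority = NA_integer_,
               volume = cn$volume, type = cn$kind, goal = fmt(cn$limit),
               parameters = "", stringsAsFactors = FALSE))
  orow <- lapply(w$objectives, function(ob) {
    par <- switch(ob$kind,
      "LTCP" = sprintf("Dp = %g Gy, alpha = %g", ob$params$Dp,
                       ob$params$alpha),
      "EUD" = sprintf("k = %g", ob$params$k),
      "dose-volume" = sprintf("threshold = %s", fmt(ob$params$threshold)),
      "")
    goal <- if (ob$kind == "dose-volume") sprintf("%g%%", ob$goal)
            else if (ob$kind == "LTCP") sprintf("%g", ob$goal)
            else fmt(ob$goal)
    data.frame(block = "objective", priority = as.integer(ob$priority),
               volume = ob$volume, type = ob$kind, goal = goal,
               parameters = par, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(crow, orow))
}

#' @export
print.wishlist <- function(x, ...) {
  cat(sprintf("<wishlist> prescription %g Gy in %d fractions, relaxation %g\n",
              x$prescription$dose_gy, x$prescription$n_fractions,
              x$relaxation))
  print(wishlist_table(x), row.names = FALSE)
  invisible(x)
}
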