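# Recording-container and model I/O. Recordings (stimulus + trial
# responses + metadata) round-trip bitwise through RDS; models serialize
# to JSON (full-precision doubles) with their basis definitions,
# coefficients and constraint flags, so a reloaded model reproduces
# predictions bitwise.

#' Write / read a recording container
#'
#' The container holds the stimulus (values, dt, schedule, repeat
#' windows), current trials and/or spike trials, and provenance metadata.
#' Round trip is lossless (bitwise).
#'
#' @param recording a \code{recording} (see
#'   \code{\link{generate_recording}}).
#' @param path file path (conventionally \code{.rds}).
#' @return \code{read_recording} returns the \code{recording}.
#' @export
write_recording <- function(recording, path) {
  if (!inherits(recording, "recording"))
    stop_invalid("not a recording object")
  obj <- list(schema = "divsenc-recording", version = 1L,
              recording = recording)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop_invalid("cannot read container: ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$schema, "divsenc-recording"))
    stop_invalid("schema error: not a divsenc recording container")
  if (obj$version > 1L)
    stop_invalid("schema error: unsupported container version ",
                 obj$version)
  rec <- obj$recording
  if (is.null(rec$stim))
    stop_invalid("schema error: container is missing the stimulus")
  rec
}

# ---- model JSON ------------------------------------------------------------

basis_to_list <- function(b)
  list(n_funcs = b$n_funcs, t_max = b$t_max, dt = b$dt)

filter_to_list <- function(f)
  list(coeffs = as.numeric(f$coeffs), n_channels = f$n_channels,
       basis = basis_to_list(f$basis), normalized = isTRUE(f$normalized))

filter_from_list <- function(l) {
  b <- temporal_basis(l$basis$n_funcs, l$basis$t_max, l$basis$dt)
  temporal_filter(matrix(unlist(l$coeffs), ncol = l$n_channels), b,
                  normalize = FALSE)
}

nl_to_list <- function(nl)
  list(knots = nl$basis$knots, weights = nl$weights,
       constraint = nl$constraint)

nl_from_list <- function(l)
  nonlinearity(tent_basis(unlist(l$knots)), unlist(l$weights),
               l$constraint)

#' Serialize a fitted model to JSON
#'
#' All model families round-trip losslessly: basis definitions,
#' coefficients, constraint flags, offsets and the fit log are stored at
#' full double precision.
#'
#' @param model a fitted model (LN, DivS, AddS, 2-D, LNK or spiking).
#' @param path output path (\code{.json}).
#' @export
write_model <- function(model, path) {
  l <- model_to_list(model)
  jsonlite::write_json(l, path, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  model_from_list(l)
}

model_to_list <- function(model) {
  kind <- model$kind
  core <- switch(kind,
    ln = list(filter = filter_to_list(model$filter),
              nonlinearity = nl_to_list(model$nonlinearity),
              offset = model$offset),
    divs = ,
    adds = list(exc_filter = filter_to_list(model$exc$filter),
                exc_nl = nl_to_list(model$exc$nonlinearity),
                sup_filter = filter_to_list(model$sup$filter),
                sup_nl = nl_to_list(model$sup$nonlinearity),
                offset = model$offset),
    `2d` = list(exc_filter = filter_to_list(model$filters$exc),
                sup_filter = filter_to_list(model$filters$sup),
                grid_x = model$basis$grid_x, grid_y = model$basis$grid_y,
                weights = as.numeric(model$weights),
                density = as.numeric(model$density)),
    lnk = list(filter = filter_to_list(model$filter),
               input_nl = nl_to_list(model$input_nl),
               u_max = model$u_max, k_ai = model$k_ai, k_ir = model$k_ir,
               gain = model$gain, offset = model$offset),
    glm = ,
    divs_rp = ,
    divs_spike = list(
      subunits = lapply(model$subunits, function(su) {
        if (su$kind == "linear")
          list(kind = "linear", filter = filter_to_list(su$filter))
        else
          list(kind = "divs",
               exc_filter = filter_to_list(su$exc$filter),
               exc_nl = nl_to_list(su$exc$nonlinearity),
               sup_filter = filter_to_list(su$sup$filter),
               sup_nl = nl_to_list(su$sup$nonlinearity))
      }),
      history = if (is.null(model$history)) NULL else
        list(kernel = model$history$kernel,
             coeffs = model$history$coeffs),
      theta = model$theta),
    stop_invalid("unsupported model kind: ", kind))
  c(list(schema = "divsenc-model", version = 1L, kind = kind,
         fit_log = as.numeric(model$mse_log %||% model$ll_log)), core)
}

model_from_list <- function(l) {
  if (!identical(l$schema, "divsenc-model"))
    stop_invalid("schema error: not a divsenc model file")
  kind <- l$kind
  fl <- as.numeric(unlist(l$fit_log))
  switch(kind,
    ln = structure(list(filter = filter_from_list(l$filter),
                        nonlinearity = nl_from_list(l$nonlinearity),
                        offset = l$offset, mse_log = fl, kind = "ln"),
                   class = "ln_model"),
    divs = ,
    adds = structure(list(
      exc = list(filter = filter_from_list(l$exc_filter),
                 nonlinearity = nl_from_list(l$exc_nl)),
      sup = list(filter = filter_from_list(l$sup_filter),
                 nonlinearity = nl_from_list(l$sup_nl)),
      offset = l$offset, mse_log = fl, kind = kind),
      class = paste0(kind, "_model")),
    `2d` = {
      gx <- unlist(l$grid_x); gy <- unlist(l$grid_y)
      structure(list(
        filters = list(exc = filter_from_list(l$exc_filter),
                       sup = filter_from_list(l$sup_filter)),
        basis = pyramid_basis_2d(gx, gy),
        weights = matrix(unlist(l$weights), length(gx), length(gy)),
        density = matrix(unlist(l$density), length(gx), length(gy)),
        mse_log = fl, kind = "2d"), class = "model2d")
    },
    lnk = lnk_model(filter_from_list(l$filter), nl_from_list(l$input_nl),
                    l$u_max, l$k_ai, l$k_ir, l$gain, l$offset),
    glm = ,
    divs_rp = ,
    divs_spike = {
      sus <- lapply(l$subunits, function(su) {
        if (su$kind == "linear")
          list(kind = "linear", filter = filter_from_list(su$filter))
        else
          list(kind = "divs",
               exc = list(filter = filter_from_list(su$exc_filter),
                          nonlinearity = nl_from_list(su$exc_nl)),
               sup = list(filter = filter_from_list(su$sup_filter),
                          nonlinearity = nl_from_list(su$sup_nl)))
      })
      hist <- if (is.null(l$history)) NULL else
        list(basis = NULL, coeffs = unlist(l$history$coeffs),
             kernel = as.numeric(unlist(l$history$kernel)))
      structure(list(subunits = sus, history = hist, theta = l$theta,
                     ll_log = fl, kind = kind, train_ll = NA_real_),
                class = "spiking_model")
    },
    stop_invalid("unsupported model kind in file: ", kind))
}
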