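#' Architecture configuration
#'
#' Describes the three-branch decoder: a temporal-convolution front end
#' feeding a graph-convolution branch, a grouped spatial-convolution branch
#' on the raw band tensor, and an LSTM branch on the averaged spatial
#' features, fused by elementwise summation into a linear classifier with
#' log-softmax output.
#'
#' Defaults mirror the full-scale architecture for 204 gradiometers at
#' 500 Hz (T = 2500): kernel (1,10) with 9 temporal filters, max-pool
#' (1,10), graph layers (64,5), 288 spatial filters in 9 band groups,
#' temporal averaging window 500, LSTM hidden size 32, dropout 0.25.
#'
#' @param n_channels,n_times,n_bands,n_classes data dimensions.
#' @param temporal_conv_kernel,temporal_conv_filters front-end temporal
#'   convolution kernel length and output maps.
#' @param pool_factor max-pool width/stride over time (must divide
#'   `n_times`).
#' @param gcn_dims lengths of the two graph-layer outputs.
#' @param spatial_filters,spatial_groups grouped spatial convolution: total
#'   filters and groups; `spatial_groups` must equal `n_bands` (one band per
#'   group) and divide `spatial_filters`.
#' @param avg_window non-overlapping temporal averaging window (must divide
#'   `n_times`); the fused feature map has `n_times / avg_window` steps.
#' @param lstm_hidden LSTM hidden size (projected back to
#'   `spatial_filters` dims per step).
#' @param dropout_p dropout probability in `[0,1)`.
#' @param adjacency an `adjacency_spec` for the sensor graph (required to
#'   build unless the GCN branch is ablated).
#' @param drop which branch contribution to omit from the fusion:
#'   `"none"`, `"module1_gcn"`, `"module2_spatialconv"`, `"module3_lstm"`.
#'   Normally set via [ablate()].
#' @return a `glcnet_config`.
#' @export
glcnet_config <- function(n_channels = 204L, n_times = 2500L, n_bands = 9L,
                          n_classes = 4L,
                          temporal_conv_kernel = 10L,
                          temporal_conv_filters = 9L,
                          pool_factor = 10L,
                          gcn_dims = c(64L, 5L),
                          spatial_filters = 288L,
                          spatial_groups = 9L,
                          avg_window = 500L,
                          lstm_hidden = 32L,
                          dropout_p = 0.25,
                          adjacency = NULL,
                          drop = c("none", "module1_gcn",
                                   "module2_spatialconv", "module3_lstm")) {
  drop <- match.arg(drop)
  cfg <- list(n_channels = as.integer(n_channels),
              n_times = as.integer(n_times),
              n_bands = as.integer(n_bands),
              n_classes = as.integer(n_classes),
              temporal_conv_kernel = as.integer(temporal_conv_kernel),
              temporal_conv_filters = as.integer(temporal_conv_filters),
              pool_factor = as.integer(pool_factor),
              gcn_dims = as.integer(gcn_dims),
              spatial_filters = as.integer(spatial_filters),
              spatial_groups = as.integer(spatial_groups),
              avg_window = as.integer(avg_window),
              lstm_hidden = as.integer(lstm_hidden),
              dropout_p = as.numeric(dropout_p),
              adjacency = adjacency,
              drop = drop)
  class(cfg) <- "glcnet_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "glcnet_config"))
  with(cfg, {
    if (n_times %% pool_factor != 0)
      stop("n_times must be divisible by pool_factor")
    if (n_times %% avg_window != 0)
      stop("n_times must be divisible by avg_window")
    if (spatial_filters %% spatial_groups != 0)
      stop("spatial_filters must be divisible by spatial_groups")
    if (spatial_groups != n_bands)
      stop("spatial_groups must equal n_bands (one band per group)")
    if (length(gcn_dims) != 2L || any(gcn_dims < 1L))
      stop("gcn_dims must be two positive integers")
    if (dropout_p < 0 || dropout_p >= 1)
      stop("dropout_p must lie in [0,1)")
    if (any(c(n_channels, n_times, n_bands, n_classes,
              temporal_conv_kernel, temporal_conv_filters,
              pool_factor, avg_window, lstm_hidden) < 1L))
      stop("all dimensions must be >= 1")
  })
  cfg
}

# derived dimensions
cfg_dims <- function(cfg) {
  list(P = cfg$n_times %/% cfg$pool_factor,        # GCN node feature dim
       Q = cfg$n_times %/% cfg$avg_window,         # fused time steps
       Gf = cfg$spatial_filters %/% cfg$spatial_groups,
       F0 = cfg$temporal_conv_filters,
       Fsp = cfg$spatial_filters)
}

uinit <- function(dims, fan_in) {
  bound <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -bound, bound), dims)
}

has_branch <- function(cfg, which) {
  switch(which,
         gcn = cfg$drop != "module1_gcn",
         spatial = TRUE,  # spatial conv always built (feeds the LSTM) ...
         spatial_fused = cfg$drop != "module2_spatialconv",
         lstm = cfg$drop != "module3_lstm")
}

#' Build the decoder
#'
#' Instantiates all trainable arrays (uniform fan-in initialization from
#' the current RNG state; seed with [set_global_seed()] for
#' reproducibility), the batch-norm running statistics, and the normalized
#' graph propagation matrix.  Sub-modules are named `frontend`,
#' `gcn_branch`, `spatial_branch`, `lstm_branch`, `classifier`; every
#' trainable scalar belongs to exactly one of them.
#'
#' @param config a [glcnet_config()]; `config$adjacency` must be set unless
#'   the GCN branch is ablated.
#' @return a `glcnet_model`.
#' @export
build_glcnet <- function(config) {
  cfg <- validate_config(config)
  d <- cfg_dims(cfg)
  C <- cfg$n_channels; B <- cfg$n_bands; K0 <- cfg$temporal_conv_kernel
  G1 <- cfg$gcn_dims[1L]; G2 <- cfg$gcn_dims[2L]
  H <- cfg$lstm_hidden; Nc <- cfg$n_classes
  prop <- NULL
  params <- list()
  state <- list()
  if (has_branch(cfg, "gcn")) {
    if (is.null(cfg$adjacency))
      stop("config$adjacency is required for the GCN branch")
    if (nrow(cfg$adjacency$matrix) != C)
      stop(sprintf("adjacency is %dx%d but n_channels is %d",
                   nrow(cfg$adjacency$matrix), ncol(cfg$adjacency$matrix), C))
    prop <- normalize_adjacency(cfg$adjacency)
    params$fe_W <- uinit(c(d$F0, B, K0), B * K0)
    params$fe_b <- numeric(d$F0)
    params$fe_bn_g <- rep(1, d$F0); params$fe_bn_b <- numeric(d$F0)
    params$g1_W <- uinit(c(d$P, G1), d$P); params$g1_b <- numeric(G1)
    params$g2_W <- uinit(c(G1, G2), G1); params$g2_b <- numeric(G2)
    params$gc_W <- uinit(c(d$Fsp, d$F0 * C), d$F0 * C)
    params$gc_b <- numeric(d$Fsp)
    params$gc_bn_g <- rep(1, d$Fsp); params$gc_bn_b <- numeric(d$Fsp)
    state$fe_bn_mean <- numeric(d$F0); state$fe_bn_var <- rep(1, d$F0)
    state$gc_bn_mean <- numeric(d$Fsp); state$gc_bn_var <- rep(1, d$Fsp)
  }
  params$sp_W <- uinit(c(d$Gf, C, cfg$spatial_groups), C)
  params$sp_b <- numeric(d$Fsp)
  params$sp_bn_g <- rep(1, d$Fsp); params$sp_bn_b <- numeric(d$Fsp)
  state$sp_bn_mean <- numeric(d$Fsp); state$sp_bn_var <- rep(1, d$Fsp)
  if (has_branch(cfg, "lstm")) {
    params$ls_Wx <- uinit(c(4L * H, d$Fsp), H)
    params$ls_Wh <- uinit(c(4L * H, H), H)
    params$ls_b <- numeric(4L * H)
    params$ls_Wr <- uinit(c(d$Fsp, H), H)
    params$ls_br <- numeric(d$Fsp)
  }
  params$cl_W <- uinit(c(Nc, d$Fsp * d$Q), d$Fsp * d$Q)
  params$cl_b <- numeric(Nc)
  structure(list(config = cfg, params = params, state = state, prop = prop),
            class = "glcnet_model")
}

submodule_of <- function(name) {
  prefix <- sub("_.*$", "", name)
  switch(prefix,
         fe = "frontend",
         g1 = "gcn_branch", g2 = "gcn_branch", gc = "gcn_branch",
         sp = "spatial_branch",
         ls = "lstm_branch",
         cl = "classifier",
         stop(sprintf("unknown parameter %s", name)))
}

#' Count trainable parameters
#'
#' @param model a `glcnet_model`.
#' @param submodule `"all"`, one of `"frontend"`, `"gcn_branch"`,
#'   `"spatial_branch"`, `"lstm_branch"`, `"classifier"`, or a single
#'   parameter name (e.g. `"gc_W"`).
#' @return integer count of trainable scalars.
#' @export
count_parameters <- function(model, submodule = "all") {
  stopifnot(inherits(model, "glcnet_model"))
  known <- c("frontend", "gcn_branch", "spatial_branch", "lstm_branch",
             "classifier")
  sizes <- vapply(model$params, length, 0L)
  owners <- vapply(names(sizes), submodule_of, "")
  if (submodule == "all") return(sum(sizes))
  if (submodule %in% known) return(sum(sizes[owners == submodule]))
  if (submodule %in% names(sizes)) return(sizes[[submodule]])
  valid <- c("all", known, names(sizes))
  stop(sprintf("unknown sub-module '%s'; valid: %s", submodule,
               paste(valid, collapse = ", ")))
}

#' Parameter registry
#'
#' @param model a `glcnet_model`.
#' @return data.frame with one row per parameter array: name, sub-module,
#'   dimensions, count.
#' @export
parameter_registry <- function(model) {
  stopifnot(inherits(model, "glcnet_model"))
  data.frame(
    parameter = names(model$params),
    submodule = vapply(names(model$params), submodule_of, ""),
    dims = vapply(model$params, function(p)
      paste(if (is.null(dim(p))) length(p) else dim(p), collapse = "x"), ""),
    count = vapply(model$params, length, 0L),
    row.names = NULL)
}

#' Ablate one branch
#'
#' Returns a configuration whose built model omits the named branch's
#' contribution from the fused summation: `module1_gcn` removes the
#' temporal-convolution front end and the graph branch (feature F1),
#' `module2_spatialconv` drops the spatial feature F3 from the fusion while
#' retaining the spatial convolution that feeds the LSTM, and
#' `module3_lstm` drops the recurrent feature F2.  The classifier width is
#' unchanged.
#'
#' @param config a [glcnet_config()] with `drop == "none"`.
#' @param remove one of `"module1_gcn"`, `"module2_spatialconv"`,
#'   `"module3_lstm"`.
#' @return a modified `glcnet_config`.
#' @export
ablate <- function(config,
                   remove = c("module1_gcn", "module2_spatialconv",
                              "module3_lstm")) {
  remove <- match.arg(remove)
  cfg <- validate_config(config)
  if (cfg$drop != "none")
    stop("only one module may be removed at a time")
  cfg$drop <- remove
  cfg
}
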