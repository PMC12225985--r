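#' Save a network bundle to a portable checkpoint
#'
#' Single-file JSON checkpoint: config, seed, and every parameter matrix
#' base64-encoded as little-endian doubles. Numeric configuration fields
#' are encoded the same way so the round trip is bit-exact and a loaded
#' bundle reproduces inference to the last bit.
#'
#' @param bundle an `aegan_bundle`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
save_bundle <- function(bundle, path) {
  enc_vec <- function(v) jsonlite::base64_enc(
    writeBin(as.vector(as.numeric(v)), raw(), size = 8, endian = "little"))
  enc <- lapply(bundle$params, function(m) {
    list(dim = dim(m), data = enc_vec(m))
  })
  cfg <- bundle$config
  g <- cfg$grid
  num_fields <- c("bg_center", "bg_scale", "r_scale", "fwd_out_scale",
                  "rmax_scale", "output_blur", "radial_radii",
                  "radial_tau", "gate_floor")
  cfg_num <- lapply(cfg[num_fields], enc_vec)
  cfg_plain <- cfg[c("preset", "feat", "token_dim", "dec", "fwd", "disc",
                     "n_blocks", "n_heads", "n_tokens")]
  payload <- list(
    config = cfg_plain,
    inputs_enabled = as.list(cfg$inputs_enabled),
    config_num = cfg_num,
    grid = list(shape = c(g$nx, g$ny, g$nz),
                pitch = enc_vec(c(g$dx, g$dy, g$dz)),
                origin = enc_vec(g$origin)),
    seed = bundle$seed, params = enc)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Load a network bundle from a checkpoint
#'
#' @param path file written by [save_bundle()].
#' @return an `aegan_bundle`.
#' @export
load_bundle <- function(path) {
  payload <- jsonlite::fromJSON(paste(readLines(path), collapse = ""),
                                simplifyVector = TRUE)
  dec_vec <- function(s, n) readBin(jsonlite::base64_dec(s),
                                    what = "double", n = n, size = 8,
                                    endian = "little")
  shp <- as.integer(payload$grid$shape)
  pitch <- dec_vec(payload$grid$pitch, 3)
  origin <- dec_vec(payload$grid$origin, 3)
  cfg <- payload$config
  cfg$grid <- recon_grid(shp[1], shp[2], shp[3], pitch[1], pitch[2],
                         pitch[3], origin)
  cfg$inputs_enabled <- unlist(payload$inputs_enabled)
  lens <- c(bg_center = 2, bg_scale = 2, r_scale = 1, fwd_out_scale = 1,
            rmax_scale = 1, output_blur = 3, radial_radii = NA,
            radial_tau = 1, gate_floor = 1)
  for (nm in names(lens)) {
    raw_len <- length(jsonlite::base64_dec(payload$config_num[[nm]])) / 8
    cfg[[nm]] <- dec_vec(payload$config_num[[nm]], raw_len)
  }
  cfg$disc <- as.integer(cfg$disc)
  cfg$blur_kernels <- list(
    blur_matrix(cfg$grid$nx, cfg$output_blur[1]),
    blur_matrix(cfg$grid$ny, cfg$output_blur[2]),
    blur_matrix(cfg$grid$nz, cfg$output_blur[3]))
  class(cfg) <- "aegan_config"
  params <- lapply(payload$params, function(e) {
    matrix(dec_vec(e$data, prod(e$dim)), e$dim[1], e$dim[2])
  })
  structure(list(params = params, config = cfg,
                 seed = as.integer(payload$seed)),
            class = "aegan_bundle")
}
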