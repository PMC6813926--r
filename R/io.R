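# Mesh, XML-configuration and weather-CSV input/output.

#' Read a triangle mesh into the context
#'
#' Supports ASCII PLY (element vertex / element face) and Wavefront OBJ
#' (`v`/`f` records); polygonal faces are fan-triangulated on read. The
#' format is taken from the file extension unless given.
#'
#' @param ctx A `cf_context`.
#' @param path File path.
#' @param format `"PLY"`, `"OBJ"`, or `NULL` to infer from the extension.
#' @param optical Optional per-band optical properties for all triangles.
#' @return Integer vector of new triangle uuids.
#' @export
read_mesh <- function(ctx, path, format = NULL, optical = NULL) {
  if (is.null(format)) {
    ext <- toupper(tools::file_ext(path))
    if (!ext %in% c("PLY", "OBJ")) {
      stop("unknown mesh extension '", ext, "'; expected .ply or .obj")
    }
    format <- ext
  }
  format <- toupper(format)
  tri <- switch(format, PLY = .read_ply(path), OBJ = .read_obj(path),
                stop("unsupported mesh format: ", format))
  add_triangles(ctx, tri$v0, tri$v1, tri$v2, optical = optical)
}

#' Write primitives to a triangle mesh file
#'
#' Patches are written as two triangles each. Round-tripping preserves
#' vertex coordinates to float precision and triangle count exactly.
#'
#' @param ctx A `cf_context`.
#' @param path Output file path.
#' @param format `"PLY"` or `"OBJ"` (default from extension).
#' @param uuids Primitives to export (default: all planar).
#' @export
write_mesh <- function(ctx, path, format = NULL, uuids = NULL) {
  if (is.null(format)) {
    ext <- toupper(tools::file_ext(path))
    if (!ext %in% c("PLY", "OBJ")) {
      stop("unknown mesh extension '", ext, "'; expected .ply or .obj")
    }
    format <- ext
  }
  format <- toupper(format)
  if (is.null(uuids)) {
    uuids <- context_uuids(ctx)
    uuids <- uuids[ctx$kind[uuids] %in% c(1L, 2L)]
  }
  tris <- list()
  for (u in uuids) {
    v <- primitive_vertices(ctx, u)
    if (ctx$kind[u] == 1L) {
      tris[[length(tris) + 1L]] <- v
    } else if (ctx$kind[u] == 2L) {
      tris[[length(tris) + 1L]] <- v[c(1, 2, 3), ]
      tris[[length(tris) + 1L]] <- v[c(1, 3, 4), ]
    }
  }
  nt <- length(tris)
  verts <- do.call(rbind, tris)
  if (format == "PLY") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", 3L * nt),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nt),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", verts[, 1], verts[, 2], verts[, 3]), con)
    i0 <- (seq_len(nt) - 1L) * 3L
    writeLines(sprintf("3 %d %d %d", i0, i0 + 1L, i0 + 2L), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# canopyflux mesh export", con)
    writeLines(sprintf("v %.9g %.9g %.9g", verts[, 1], verts[, 2], verts[, 3]), con)
    i0 <- (seq_len(nt) - 1L) * 3L + 1L
    writeLines(sprintf("f %d %d %d", i0, i0 + 1L, i0 + 2L), con)
  }
  invisible(path)
}

.read_ply <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (length(ln) == 0 || trimws(ln[1]) != "ply") {
    stop("not a PLY file (line 1): ", path)
  }
  hdr_end <- which(trimws(ln) == "end_header")[1]
  if (is.na(hdr_end)) stop("PLY parse error: missing end_header")
  hdr <- ln[seq_len(hdr_end)]
  if (!any(grepl("^format\\s+ascii", trimws(hdr)))) {
    stop("only ASCII PLY is supported (line 2)")
  }
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex",
                                                       trimws(hdr), value = TRUE)))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face",
                                                     trimws(hdr), value = TRUE)))
  if (length(nv) != 1 || is.na(nv)) stop("PLY parse error: no vertex element in header")
  if (length(nf) != 1 || is.na(nf)) stop("PLY parse error: no face element in header")
  body <- ln[(hdr_end + 1L):length(ln)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) {
    stop(sprintf("PLY parse error: expected %d data lines, found %d (after line %d)",
                 nv + nf, length(body), hdr_end))
  }
  vl <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- matrix(as.numeric(unlist(lapply(vl, `[`, 1:3))), nv, 3L, byrow = TRUE)
  if (anyNA(verts)) {
    stop("PLY parse error: non-numeric vertex near line ",
         hdr_end + which(is.na(rowSums(verts)))[1])
  }
  tri <- list()
  for (i in seq_len(nf)) {
    f <- as.integer(strsplit(trimws(body[nv + i]), "\\s+")[[1]])
    k <- f[1]
    if (is.na(k) || length(f) < k + 1) {
      stop("PLY parse error: malformed face at data line ", nv + i)
    }
    idx <- f[2:(k + 1)] + 1L
    for (j in seq_len(k - 2)) {
      tri[[length(tri) + 1L]] <- idx[c(1, j + 1, j + 2)]
    }
  }
  ti <- do.call(rbind, tri)
  list(v0 = verts[ti[, 1], , drop = FALSE], v1 = verts[ti[, 2], , drop = FALSE],
       v2 = verts[ti[, 3], , drop = FALSE])
}

.read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", ln)
  fl <- grep("^f\\s", ln)
  if (!length(vl) || !length(fl)) {
    stop("OBJ parse error: no v/f records in ", path)
  }
  verts <- t(vapply(strsplit(trimws(ln[vl]), "\\s+"), function(x) {
    as.numeric(x[2:4])
  }, numeric(3)))
  if (anyNA(verts)) {
    stop("OBJ parse error: non-numeric vertex at line ",
         vl[which(is.na(rowSums(verts)))[1]])
  }
  tri <- list()
  for (i in fl) {
    toks <- strsplit(trimws(ln[i]), "\\s+")[[1]][-1]
    idx <- as.integer(sub("/.*$", "", toks))
    if (anyNA(idx) || length(idx) < 3) stop("OBJ parse error: malformed face at line ", i)
    idx[idx < 0] <- nrow(verts) + idx[idx < 0] + 1L
    for (j in seq_len(length(idx) - 2)) {
      tri[[length(tri) + 1L]] <- idx[c(1, j + 1, j + 2)]
    }
  }
  ti <- do.call(rbind, tri)
  list(v0 = verts[ti[, 1], , drop = FALSE], v1 = verts[ti[, 2], , drop = FALSE],
       v2 = verts[ti[, 3], , drop = FALSE])
}

#' Read a weather time-series CSV and attach it to the context
#'
#' Expects an ISO-8601 `time` column plus named numeric columns (typically
#' `Ta_C`, `RH`, optionally `S_dn`, `S_diff`, `L_dn`).
#'
#' @param ctx A `cf_context`.
#' @param path CSV path.
#' @return The parsed data.frame, invisibly.
#' @export
read_weather_csv <- function(ctx, path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time" %in% names(df)) stop("weather CSV needs a 'time' column")
  df$time <- as.POSIXct(df$time, tz = "UTC")
  if (anyNA(df$time)) stop("unparseable ISO-8601 timestamps in ", path)
  add_timeseries(ctx, df)
  invisible(df)
}

# --------------------------------------------------------------- XML config

.xml_num <- function(node, attr) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) {
    stop(sprintf("XML schema error: <%s> is missing required attribute '%s'",
                 xml2::xml_name(node), attr))
  }
  out <- suppressWarnings(as.numeric(strsplit(trimws(v), "\\s+")[[1]]))
  if (anyNA(out)) {
    stop(sprintf("XML schema error: <%s> attribute '%s' is not numeric",
                 xml2::xml_name(node), attr))
  }
  out
}

#' Read a simulation configuration XML
#'
#' Documented dialect (root `<canopyflux>`): `<patch center size rotation>`
#' and `<triangle v0 v1 v2>` geometry elements with nested
#' `<optical band rho tau eps>`; `<weather file>` pointing to a CSV;
#' `<band name collimated diffuse emission>`; `<physiology>` holding
#' `<stomatal E_m i_0 k b>` and `<fvcb R_d25 V_cmax25 J_max25 C_Jmax
#' dHa_Jmax alpha>`; `<simulation>` attributes copied into the returned
#' parameter list.
#'
#' @param path XML file path.
#' @return List with `ctx` (populated context), `bands`, `stomatal`, `fvcb`,
#'   `simulation` (named list of numeric attributes), `weather_file`.
#' @export
read_xml_config <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "canopyflux") {
    stop("XML schema error: root element must be <canopyflux>, found <",
         xml2::xml_name(doc), ">")
  }
  ctx <- context_create()
  get_optics <- function(node) {
    ops <- xml2::xml_find_all(node, "optical")
    if (length(ops) == 0) return(NULL)
    out <- list()
    for (o in ops) {
      b <- xml2::xml_attr(o, "band")
      if (is.na(b)) stop("XML schema error: <optical> is missing required attribute 'band'")
      out[[b]] <- c(.xml_num(o, "rho"), .xml_num(o, "tau"), .xml_num(o, "eps"))
    }
    out
  }
  for (nd in xml2::xml_find_all(doc, "patch")) {
    rot <- if (is.na(xml2::xml_attr(nd, "rotation"))) c(0, 0) else .xml_num(nd, "rotation")
    add_patch(ctx, .xml_num(nd, "center"), .xml_num(nd, "size"), rot,
              optical = get_optics(nd))
  }
  for (nd in xml2::xml_find_all(doc, "triangle")) {
    add_triangle(ctx, .xml_num(nd, "v0"), .xml_num(nd, "v1"),
                 .xml_num(nd, "v2"), optical = get_optics(nd))
  }
  bands <- list()
  for (nd in xml2::xml_find_all(doc, "band")) {
    nm <- xml2::xml_attr(nd, "name")
    if (is.na(nm)) stop("XML schema error: <band> is missing required attribute 'name'")
    bands[[nm]] <- radiation_band(
      nm,
      collimated_flux = if (is.na(xml2::xml_attr(nd, "collimated"))) 0 else .xml_num(nd, "collimated"),
      diffuse_flux = if (is.na(xml2::xml_attr(nd, "diffuse"))) 0 else .xml_num(nd, "diffuse"),
      emission = isTRUE(xml2::xml_attr(nd, "emission") == "true"))
  }
  sp <- NULL; fp <- NULL
  phys <- xml2::xml_find_first(doc, "physiology")
  if (!inherits(phys, "xml_missing")) {
    snd <- xml2::xml_find_first(phys, "stomatal")
    if (!inherits(snd, "xml_missing")) {
      sp <- stomatal_params(.xml_num(snd, "E_m"), .xml_num(snd, "i_0"),
                            .xml_num(snd, "k"), .xml_num(snd, "b"))
    }
    fnd <- xml2::xml_find_first(phys, "fvcb")
    if (!inherits(fnd, "xml_missing")) {
      fp <- fvcb_params(R_d25 = .xml_num(fnd, "R_d25"),
                        V_cmax25 = .xml_num(fnd, "V_cmax25"),
                        J_max25 = .xml_num(fnd, "J_max25"),
                        C_Jmax = .xml_num(fnd, "C_Jmax"),
                        dHa_Jmax = .xml_num(fnd, "dHa_Jmax"),
                        alpha = .xml_num(fnd, "alpha"))
    }
  }
  sim <- list()
  snode <- xml2::xml_find_first(doc, "simulation")
  if (!inherits(snode, "xml_missing")) {
    at <- xml2::xml_attrs(snode)
    sim <- lapply(as.list(at), function(x) {
      y <- suppressWarnings(as.numeric(x)); if (is.na(y)) x else y
    })
  }
  wf <- xml2::xml_find_first(doc, "weather")
  weather_file <- if (!inherits(wf, "xml_missing")) xml2::xml_attr(wf, "file") else NULL
  list(ctx = ctx, bands = bands, stomatal = sp, fvcb = fp, simulation = sim,
       weather_file = weather_file)
}

#' Write a context's geometry (and optional parameters) as configuration XML
#'
#' Writes every live patch/triangle with its per-band optical properties in
#' the dialect read by [read_xml_config()]; a configuration round-trip is
#' lossless.
#'
#' @param path Output path.
#' @param ctx A `cf_context`.
#' @param stomatal,fvcb Optional parameter objects to embed.
#' @param simulation Optional named list of scalar simulation attributes.
#' @export
write_xml_state <- function(path, ctx, stomatal = NULL, fvcb = NULL,
                            simulation = NULL) {
  doc <- xml2::xml_new_root("canopyflux")
  fmt <- function(x) paste(sprintf("%.10g", x), collapse = " ")
  add_optics <- function(node, uuid) {
    for (b in ls(ctx$optical)) {
      v <- ctx$optical[[b]][uuid, ]
      if (!anyNA(v)) {
        xml2::xml_add_child(node, "optical", band = b, rho = fmt(v[1]),
                            tau = fmt(v[2]), eps = fmt(v[3]))
      }
    }
  }
  for (u in context_uuids(ctx)) {
    v <- primitive_vertices(ctx, u)
    if (ctx$kind[u] == 2L) {
      cen <- colMeans(v)
      e1 <- v[2, ] - v[1, ]; e2 <- v[4, ] - v[1, ]
      n <- ctx$normal[u, ]
      zen <- acos(min(1, max(-1, n[3])))
      az <- atan2(-e1[2], e1[1])  # e1 = (cos a, -sin a, 0)
      nd <- xml2::xml_add_child(doc, "patch", center = fmt(cen),
                                size = fmt(c(sqrt(sum(e1^2)), sqrt(sum(e2^2)))),
                                rotation = fmt(c(zen, az %% (2 * pi))))
      add_optics(nd, u)
    } else if (ctx$kind[u] == 1L) {
      nd <- xml2::xml_add_child(doc, "triangle", v0 = fmt(v[1, ]),
                                v1 = fmt(v[2, ]), v2 = fmt(v[3, ]))
      add_optics(nd, u)
    }
  }
  if (!is.null(stomatal)) {
    ph <- xml2::xml_add_child(doc, "physiology")
    xml2::xml_add_child(ph, "stomatal", E_m = fmt(stomatal$E_m),
                        i_0 = fmt(stomatal$i_0), k = fmt(stomatal$k),
                        b = fmt(stomatal$b))
    if (!is.null(fvcb)) {
      xml2::xml_add_child(ph, "fvcb", R_d25 = fmt(fvcb$R_d25),
                          V_cmax25 = fmt(fvcb$V_cmax25),
                          J_max25 = fmt(fvcb$J_max25),
                          C_Jmax = fmt(fvcb$C_Jmax),
                          dHa_Jmax = fmt(fvcb$dHa_Jmax),
                          alpha = fmt(fvcb$alpha))
    }
  } else if (!is.null(fvcb)) {
    ph <- xml2::xml_add_child(doc, "physiology")
    xml2::xml_add_child(ph, "fvcb", R_d25 = fmt(fvcb$R_d25),
                        V_cmax25 = fmt(fvcb$V_cmax25),
                        J_max25 = fmt(fvcb$J_max25), C_Jmax = fmt(fvcb$C_Jmax),
                        dHa_Jmax = fmt(fvcb$dHa_Jmax), alpha = fmt(fvcb$alpha))
  }
  if (!is.null(simulation)) {
    do.call(xml2::xml_add_child,
            c(list(doc, "simulation"),
              lapply(simulation, function(x) paste(x, collapse = " "))))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
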