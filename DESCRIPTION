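Package: stcube
Title: Space-Time Cube Projection and Rendering of Time-Varying 3D Labeled Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects time series of labeled 3D geometry (closed cell surface
    meshes or labeled voxel volumes) through a user-defined cutting plane into a
    space-time cube (STC): a 3D label grid whose axes are two in-plane spatial
    coordinates and time. Provides cross-section rasterization with object-ID
    encoding, precomputed Sobel-Feldman normal fields, opaque first-hit raycast
    rendering with Blinn-Phong shading and per-(object, time) colormap lookups,
    STC cutting (time, space and oblique), value/time/object filtering with
    lineage-aware selection propagation, and a seeded synthetic dividing-embryo
    simulator with ground-truth lineage and annotations. Includes readers and
    writers for PLY/OBJ meshes, multi-page TIFF and NRRD label volumes, lineage
    and annotation CSV tables, and PNG renders, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
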