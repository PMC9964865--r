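Package: eitrecon
Title: Electrical Impedance Tomography Simulation and Sparse Image Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and image-reconstruction toolkit for 2D electrical
    impedance tomography (EIT). Provides a complete-electrode-model finite
    element forward solver on triangulated disk meshes with 16 boundary
    electrodes, Geselowitz sensitivity (Jacobian) matrices, conductivity
    phantoms with circular inclusions, Gaussian measurement noise at
    prescribed SNR, and a family of linearized difference-imaging solvers:
    RS-FISTA (a FISTA LASSO solver warm-started by an adaptive-regularization
    Tikhonov solve), plain ISTA and FISTA, Landweber iteration, conjugate
    gradients on the normal equations, NOSER and Newton-Raphson. Includes
    SSIM, RMSE, PSNR and change-of-average-metric (CAM) evaluation, iteration
    convergence studies and noise-robustness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    glmnet,
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
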