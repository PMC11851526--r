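method,AU5,AU6,AU8,AU9,AU10,AU12,AU14,AU18
landmark_fcn_bp4d83,82.13,84.03,84.40,76.70,86.57,78.30,72.90,54.80
landmark_fcn_mesh478,82.87,86.27,89.10,77.43,87.83,80.10,75.27,55.13
image_resnet50,85.44,85.22,87.88,79.11,89.12,79.19,74.74,59.99
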