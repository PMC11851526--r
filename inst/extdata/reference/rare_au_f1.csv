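method,AU1,AU2,AU7,AU15,AU20,AU23,AU25
no_augmentation,17.11,18.02,14.21,24.55,31.11,4.98,4.17
landmark_fcn_bp4d83_augmented,36.17,25.10,33.73,43.97,49.63,19.43,10.10
landmark_fcn_mesh478_augmented,33.63,27.47,25.53,40.13,42.20,16.73,13.53
image_resnet50,39.87,31.21,35.84,46.97,53.23,25.20,24.20
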