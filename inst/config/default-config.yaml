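# trapmatch pipeline defaults.
# Camera frames are 1280x960, the matching template 200x144; neither appears
# here because they are carried by the image and template inputs themselves.
threshold: 0.4          # correlation acceptance threshold
enable_padding: yes
enable_covering: yes
max_detections: 100
pad_fill: median
morph_size: 3           # structuring element (px) for mask cleanup
theta1: 0.1734          # perimeter/area decision threshold
theta2: 25.2            # perimeter^2/area decision threshold
match_tol: 100          # detection-to-truth center tolerance (px)
seed: 1
log_level: info
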