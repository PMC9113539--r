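# Geometric constants shared across modules.
EARTH_RADIUS_M <- 6371008.8            # mean Earth radius, meters
METERS_PER_DEGREE <- pi / 180 * EARTH_RADIUS_M  # meters per degree of arc
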