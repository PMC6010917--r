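{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"id":"C1","species":"cattle"},"geometry":{"type":"Polygon","coordinates":[[[682738.5,5096755.5],[683538.5,5096755.5],[683538.5,5097555.5],[682738.5,5097555.5],[682738.5,5096755.5]]]}},{"type":"Feature","properties":{"id":"S1","species":"sheep"},"geometry":{"type":"Polygon","coordinates":[[[683538.5,5096755.5],[684338.5,5096755.5],[684338.5,5097555.5],[683538.5,5097555.5],[683538.5,5096755.5]]]}}]}
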