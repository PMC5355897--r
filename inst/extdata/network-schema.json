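{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "lifnet network document, fileFormatVersion 3",
  "type": "object",
  "required": ["fileFormatVersion", "edges", "nodes", "workspace"],
  "additionalProperties": false,
  "properties": {
    "fileFormatVersion": { "const": 3 },
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "kind"],
        "additionalProperties": false,
        "properties": {
          "id": { "type": "string" },
          "kind": {
            "enum": ["neuron", "dc_source", "ac_source", "regular_generator",
                     "poisson_generator", "event_source", "visual_input",
                     "voltmeter", "spike_detector", "firing_rate_meter"]
          },
          "label": { "type": "string" },
          "properties": {
            "type": "object",
            "description": "Kind-specific parameters in SI units; omitted parameters take the package defaults. Neuron: Cm, Rm, Vr, Vreset, Vthres, tau_r, polarity, adaptive, tau_adapt, delta_g_adapt. dc_source: amplitude. ac_source: amplitude, frequency. regular_generator / poisson_generator: rate, polarity. event_source: activation_times, polarity. visual_input: kernel {kind, H, W, ...}, stimulus (row-major 2-D array in [0,1], or array of frames), gain, polarity, frame_interval. spike_detector: window. firing_rate_meter: sigma_w, rate_min, rate_max."
          }
        }
      }
    },
    "edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["source", "target"],
        "additionalProperties": false,
        "properties": {
          "source": { "type": "string" },
          "target": { "type": "string" },
          "properties": {
            "type": "object",
            "description": "Synapse parameters (synapse edges only): peak_current (ampere, nonnegative magnitude; the sign is inherited from the source node's polarity), tau_syn (second), delay (second).",
            "additionalProperties": false,
            "properties": {
              "peak_current": { "type": "number", "minimum": 0 },
              "tau_syn": { "type": "number", "exclusiveMinimum": 0 },
              "delay": { "type": "number", "minimum": 0 }
            }
          }
        }
      }
    },
    "workspace": {
      "type": "object",
      "description": "Free-form metadata (view state, positions); preserved on round-trip, ignored by the engine. The marker units: \"SI\" is added on save."
    }
  }
}
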