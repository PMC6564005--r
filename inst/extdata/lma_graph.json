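{
  "id": "lma-default",
  "root": "q_change",
  "questions": {
    "q_change": {
      "prompt": "Do you observe a change between the neutral and the varied execution?",
      "answers": {
        "No": {"leaf": "NoChange", "category": "NoChange"},
        "Yes": "q_category"
      }
    },
    "q_category": {
      "prompt": "In which component does the change occur?",
      "answers": {
        "Effort": "q_effort",
        "Space": "q_space_where",
        "Shape": "q_shape",
        "Phrasing": "q_phrasing"
      }
    },
    "q_effort": {
      "prompt": "Which Effort element characterizes the change?",
      "answers": {
        "Direct": {"leaf": "Direct", "category": "Effort"},
        "Indirect": {"leaf": "Indirect", "category": "Effort"},
        "Quick": {"leaf": "Quick", "category": "Effort"},
        "Sustained": {"leaf": "Sustained", "category": "Effort"},
        "Light": {"leaf": "Light", "category": "Effort"},
        "Strong": {"leaf": "Strong", "category": "Effort"},
        "Bound": {"leaf": "Bound", "category": "Effort"},
        "Free": {"leaf": "Free", "category": "Effort"}
      }
    },
    "q_space_where": {
      "prompt": "Where does the change in Space occur?",
      "answers": {
        "Zone": "q_zone",
        "Reach": "q_reach"
      }
    },
    "q_zone": {
      "prompt": "Towards which zone of the kinesphere does the movement change?",
      "answers": {
        "Up": {"leaf": "Up", "category": "Space"},
        "Down": {"leaf": "Down", "category": "Space"},
        "Forward": {"leaf": "Forward", "category": "Space"},
        "Backward": {"leaf": "Backward", "category": "Space"},
        "Side-Open": {"leaf": "Side-Open", "category": "Space"},
        "Side-Across": {"leaf": "Side-Across", "category": "Space"}
      }
    },
    "q_reach": {
      "prompt": "Which reach of the kinesphere does the movement change to?",
      "answers": {
        "Far": {"leaf": "Far", "category": "Space"},
        "Mid": {"leaf": "Mid", "category": "Space"},
        "Near": {"leaf": "Near", "category": "Space"}
      }
    },
    "q_shape": {
      "prompt": "Which Shape quality characterizes the change?",
      "answers": {
        "Rising": {"leaf": "Rising", "category": "Shape"},
        "Sinking": {"leaf": "Sinking", "category": "Shape"},
        "Spreading": {"leaf": "Spreading", "category": "Shape"},
        "Enclosing": {"leaf": "Enclosing", "category": "Shape"},
        "Advancing": {"leaf": "Advancing", "category": "Shape"},
        "Retreating": {"leaf": "Retreating", "category": "Shape"}
      }
    },
    "q_phrasing": {
      "prompt": "Where does the emphasis fall within the phrase?",
      "answers": {
        "Impulsive": {"leaf": "Impulsive", "category": "Phrasing"},
        "Swing": {"leaf": "Swing", "category": "Phrasing"},
        "Impactive": {"leaf": "Impactive", "category": "Phrasing"}
      }
    }
  },
  "aliases": {
    "bound": "Bound",
    "direct": "Direct",
    "free": "Free",
    "light": "Light",
    "quick": "Quick",
    "strong": "Strong",
    "sustained": "Sustained",
    "impactive": "Impactive",
    "impulsive": "Impulsive",
    "swing": "Swing",
    "advancing": "Advancing",
    "enclosing": "Enclosing",
    "opening": "Spreading",
    "retreating": "Retreating",
    "rising": "Rising",
    "sinking": "Sinking",
    "far reach": "Far",
    "mid reach": "Mid",
    "near reach": "Near",
    "side-across": "Side-Across",
    "side-open": "Side-Open",
    "backwards": "Backward",
    "down": "Down",
    "up": "Up",
    "neutral": "NoChange"
  }
}
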