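{
  "Gastrointestinal symptoms": ["Change in Weight", "Nausea"],
  "Gynecologic symptoms": ["Vaginal itching", "Bleeding"],
  "Neuropsychologic symptoms": ["Headache", "Dizziness"],
  "Vasomotor symptoms": ["Sweating", "Hot flashes"],
  "Musculoskeletal symptoms": ["Joint pain", "Muscle aches"],
  "Integumentary symptoms": ["Rash", "Hair loss"],
  "Cardiorespiratory symptoms": ["Trouble breathing", "Chest pain"],
  "Distress symptoms": ["Nervousness", "Depression"],
  "Despair symptoms": ["Feeling worthless", "Hopelessness"]
}
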