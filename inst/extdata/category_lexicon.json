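{
  "confusion_negative_emotions": ["confus", "worri", "worry", "anxi", "fear", "afraid", "scare", "scari", "sad", "angry", "anger", "upset", "stress", "overwhelm", "uncertain", "dread", "hopeless", "frustrat", "nervous", "panick", "cry", "despair"],
  "health_medical": ["health", "sick", "ill", "doctor", "hospital", "symptom", "medic", "nurse", "emergen", "fever", "cough", "breath", "clinic", "disease", "infect", "vaccin", "patient"],
  "work_economic": ["work", "job", "business", "econom", "money", "pay", "unemploy", "boss", "office", "income", "layoff", "laid", "rent", "financ", "career", "salary", "bill"],
  "technology_internet": ["tech", "internet", "online", "zoom", "computer", "laptop", "phone", "app", "video", "wifi", "screen", "email", "virtual", "stream", "website"],
  "cleaning_hygiene": ["clean", "wash", "sanitiz", "sanitis", "disinfect", "hygien", "soap", "mask", "glove", "wipe", "scrub", "germ"],
  "government_leadership": ["govern", "president", "leader", "policy", "politic", "state", "mayor", "governor", "law", "official", "election", "congress", "administr"],
  "traveling_shopping": ["travel", "trip", "flight", "fly", "shop", "store", "grocer", "buy", "bought", "purchas", "vacation", "airport", "mall", "order"],
  "party_celebration": ["party", "parties", "celebrat", "birthday", "wedding", "holiday", "festiv", "gather", "dance", "danci", "concert", "toast"],
  "positive_emotion_love": ["love", "lovin", "happy", "happi", "joy", "glad", "grate", "wonderful", "sweet", "hug", "kiss", "caring", "cherish", "adore"],
  "friends_children": ["friend", "child", "kid", "son", "daughter", "famil", "parent", "mom", "dad", "sibling", "buddy", "niece", "nephew", "grand"],
  "optimism": ["optimis", "hope", "hopeful", "better", "improv", "bright", "forward", "positiv", "upbeat", "confident", "encourag"]
}
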