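{
  "F45.21": {
    "label": "Hypochondriasis",
    "phrases": [
      "worries of unexplained aches and pains in the head back joints abdomen or legs",
      "feeling that illnesses are not being taken seriously enough"
    ]
  },
  "G47.00": {
    "label": "Insomnia",
    "phrases": [
      "problems with falling asleep",
      "problems with staying asleep",
      "overall poor sleep quality"
    ]
  },
  "F42.9": {
    "label": "Obsession-compulsion",
    "phrases": [
      "unpleasant thoughts urges or images that repeatedly enter the mind",
      "feeling driven to perform certain behaviors or mental acts over and over again"
    ]
  },
  "F22": {
    "label": "Paranoia",
    "phrases": [
      "feeling punished without cause",
      "feeling sure one is being talked about",
      "feeling that people are out to get you",
      "feeling one must be on guard even with friends"
    ]
  },
  "Z63.4": {
    "label": "Grief",
    "phrases": [
      "thoughts of a person who died make it hard to do things one normally does",
      "memories of a person who died are upsetting",
      "feeling longing for the person who died",
      "feeling angry about the death"
    ]
  },
  "F43.0": {
    "label": "Acute stress",
    "phrases": [
      "experiencing an especially frightening horrible or traumatic event",
      "having nightmares about the event or unwanted thoughts about the event",
      "trying hard not to think about the event or avoiding situations that are reminders of the event",
      "feeling constantly on guard watchful or easily startled",
      "feeling numb or detached from people activities or surroundings",
      "feeling guilty or unable to stop blaming oneself or others for the event"
    ]
  },
  "F43.1": {
    "label": "Posttraumatic stress disorder",
    "phrases": [
      "experiencing an especially frightening horrible or traumatic event",
      "having nightmares about the event or unwanted thoughts about the event",
      "trying hard not to think about the event or avoiding situations that are reminders of the event",
      "feeling constantly on guard watchful or easily startled",
      "feeling numb or detached from people activities or surroundings",
      "feeling guilty or unable to stop blaming oneself or others for the event"
    ]
  },
  "Z91.5": {
    "label": "Nonsuicidal self-injury",
    "phrases": [
      "deliberately hurting oneself physically without intending to kill oneself",
      "hurting oneself as a strategy for relief"
    ]
  },
  "F41.0": {
    "label": "Panic",
    "phrases": [
      "experiencing panic episodes",
      "worrying about having another panic episode"
    ]
  },
  "F40.00": {
    "label": "Agoraphobia",
    "phrases": [
      "worrying about being in a public space in which escape might not be available should excessive anxiety or panic symptoms develop",
      "obsessive persistent intense fear of open places"
    ]
  },
  "F41.9": {
    "label": "Anxiety",
    "phrases": [
      "feeling afraid as if something awful might happen",
      "not being able to stop or control worrying",
      "worrying too much about different things",
      "becoming easily annoyed or irritable"
    ]
  },
  "COVID19": {
    "label": "COVID-19-specific psychological criteria",
    "phrases": [
      "feeling unsure about whether psychological reactions are normative or problematic",
      "difficulty in controlling anger at the actions or lack of actions of others"
    ]
  }
}
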