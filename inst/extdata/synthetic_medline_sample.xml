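<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic MEDLINE-style sample for format illustration; not real data. -->
<PubmedArticleSet>
  <PubmedArticle>
    <MedlineCitation>
      <Article>
        <Journal>
          <JournalIssue>
            <PubDate><Year>2015</Year></PubDate>
          </JournalIssue>
        </Journal>
        <ArticleTitle>A synthetic three-author article</ArticleTitle>
        <AuthorList>
          <Author><LastName>Alpha</LastName><ForeName>Anna</ForeName><Initials>A</Initials></Author>
          <Author><LastName>Beta</LastName><ForeName>Bruno</ForeName><Initials>B</Initials></Author>
          <Author><LastName>Gamma</LastName><ForeName>Carla</ForeName><Initials>C</Initials></Author>
        </AuthorList>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <Article>
        <Journal>
          <JournalIssue>
            <PubDate><Year>2015</Year></PubDate>
          </JournalIssue>
        </Journal>
        <ArticleTitle>A synthetic author-less editorial</ArticleTitle>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <Article>
        <Journal>
          <JournalIssue>
            <PubDate><Year>2014</Year></PubDate>
          </JournalIssue>
        </Journal>
        <ArticleTitle>A synthetic article with a last-name-only author</ArticleTitle>
        <AuthorList>
          <Author><LastName>Delta</LastName></Author>
        </AuthorList>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
</PubmedArticleSet>
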